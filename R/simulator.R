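# Realizes an ethogram spec into labeled time-series: samples event
# sequences, renders constituents, inserts pose transitions, applies
# fluctuations and observation noise.
#
# Coordinate convention: 0-based sample indices with half-open [start, end)
# intervals in all event tables; feature matrices are ordinary 1-based R
# matrices whose row i + 1 corresponds to sample index i.

#' Sample a sequence of behavior labels
#'
#' Event labels are drawn i.i.d. uniformly over the spec's behaviors, with
#' immediate repeats resampled so every event boundary is a genuine behavior
#' change. The behavior-to-behavior transition structure carries no
#' information by construction: no sequence cue exists for a model to learn.
#'
#' @param spec An [ethogram_spec].
#' @param n_events Number of events (`>= 1`).
#' @return Character vector of `n_events` behavior labels.
#' @export
sample_event_sequence <- function(spec, n_events) {
  labels <- names(spec$behaviors)
  if (length(labels) == 0L) stop("spec has no behaviors")
  stopifnot(n_events >= 1L)
  out <- character(n_events)
  out[1L] <- sample(labels, 1L)
  if (n_events > 1L && length(labels) == 1L)
    stop("cannot avoid immediate repeats with a single behavior")
  for (i in seq_len(n_events - 1L) + 1L)
    out[i] <- sample(setdiff(labels, out[i - 1L]), 1L)
  out
}

#' Apply within-event fluctuations to a feature segment
#'
#' Adds (a) a Gaussian wander low-passed by a moving average of
#' `fl$smoothness` samples and rescaled to standard deviation `fl$amount`,
#' and (b) if a period is present, a sinusoid of `fl$period` samples and
#' amplitude `fl$period_amplitude` with one random phase for the whole
#' segment. Both components are shared design: the wander is drawn per
#' feature, the sinusoid is added to every feature.
#'
#' @param segment Numeric matrix, time by features.
#' @param fl A [fluctuation()] spec.
#' @return Matrix of the same shape.
#' @export
apply_fluctuations <- function(segment, fl) {
  segment <- as.matrix(segment)
  n <- nrow(segment)
  if (n < 1L) stop("segment must have length >= 1")
  if (fl$amount > 0) {
    w <- fl$smoothness
    for (j in seq_len(ncol(segment))) {
      raw <- stats::rnorm(n + w - 1L)
      sm <- if (w > 1L) {
        as.numeric(stats::filter(raw, rep(1 / w, w), sides = 1L))[w:(n + w - 1L)]
      } else raw
      segment[, j] <- segment[, j] + sm * sqrt(w) * fl$amount
    }
  }
  if (!is.null(fl$period)) {
    phase <- stats::runif(1L, 0, 2 * pi)
    wave <- fl$period_amplitude *
      sin(2 * pi * (seq_len(n) - 1L) / fl$period + phase)
    segment <- segment + wave
  }
  segment
}

#' Build a pose-transition segment
#'
#' Interpolates from one pose location toward another along a smooth
#' monotone cosine-ease ramp. Interior time points are strictly between the
#' endpoints, so transition samples never replicate either pose exactly,
#' and a small Gaussian scatter is added on top.
#'
#' @param prev_pose,next_pose Numeric vectors of per-feature pose locations.
#' @param len Transition length in samples, within `range`.
#' @param scatter Per-feature standard deviation of the added scatter.
#' @param range Admissible `[min, max]` length; defaults to the spec-wide
#'   `c(2, 8)`.
#' @return A `len` by `F` matrix of transition samples.
#' @export
make_transition <- function(prev_pose, next_pose, len, scatter = 0,
                            range = c(2L, 8L)) {
  if (len < range[1] || len > range[2])
    stop("transition length ", len, " outside [", range[1], ", ", range[2], "]")
  nf <- length(prev_pose)
  t <- seq_len(len) / (len + 1)
  g <- (1 - cos(pi * t)) / 2
  seg <- outer(g, next_pose - prev_pose) +
    matrix(rep(prev_pose, each = len), nrow = len)
  if (any(scatter > 0))
    seg <- seg + matrix(stats::rnorm(len * nf, 0, rep(scatter, each = len)),
                        nrow = len)
  seg
}

# Render one constituent: key-pose mean + pose scatter + within-event
# fluctuation. The scatter splits into a held per-execution offset
# (held_frac of the variance: the animal holds the pose it struck) and
# per-sample jitter, so the marginal per-sample scatter is exactly
# `spread` while the within-execution scatter does not average away.
render_constituent <- function(cn, n_features) {
  dur <- sample_duration(cn$duration)
  kp <- cn$key_pose
  s_held <- kp$spread * sqrt(kp$held_frac)
  s_jit <- kp$spread * sqrt(1 - kp$held_frac)
  offset <- stats::rnorm(n_features, 0, s_held)
  seg <- matrix(rep(kp$mean + offset, each = dur), nrow = dur) +
    matrix(stats::rnorm(dur * n_features, 0, rep(s_jit, each = dur)),
           nrow = dur)
  apply_fluctuations(seg, cn$fluctuation)
}

#' Realize one behavior event
#'
#' Draws durations and renders the behavior's constituents. Atomic behaviors
#' yield a single sub-event; ordered behaviors render their constituents in
#' sequence, joined by internal pose transitions drawn from the same length
#' range as inter-event transitions; unordered behaviors first draw a repeat
#' count, then one constituent per repeat according to the mixture weights.
#'
#' @param behavior A [behavior_def].
#' @param spec The parent [ethogram_spec] (supplies `F` and the transition
#'   range).
#' @return A list with `features` (pre-noise segment, time by `F`),
#'   `subevents` (data.frame `label`, `start`, `end`; 0-based half-open,
#'   relative to the event, tiling it exactly), and the boundary poses
#'   `first_pose`/`last_pose` used to anchor neighboring transitions.
#' @export
realize_event <- function(behavior, spec) {
  nf <- spec$n_features
  cons <- switch(behavior$structure_type,
    atomic  = behavior$constituents,
    ordered = behavior$constituents,
    unordered = {
      n_rep <- sample_duration(behavior$repeat_count)
      w <- behavior$mixture_weights
      if (is.null(w)) w <- rep(1, length(behavior$constituents))
      idx <- sample.int(length(behavior$constituents), n_rep, replace = TRUE,
                        prob = w)
      behavior$constituents[idx]
    },
    stop("unknown structure type"))
  segs <- list()
  labs <- character(0)
  trans_label <- paste0(behavior$label, ".t")
  for (k in seq_along(cons)) {
    if (k > 1L) {
      prev_kp <- cons[[k - 1L]]$key_pose
      next_kp <- cons[[k]]$key_pose
      len <- sample.int(spec$transition_range[2] - spec$transition_range[1] + 1L,
                        1L) + spec$transition_range[1] - 1L
      segs <- c(segs, list(make_transition(
        prev_kp$mean, next_kp$mean, len,
        scatter = (prev_kp$spread + next_kp$spread) / 4,
        range = spec$transition_range)))
      labs <- c(labs, trans_label)
    }
    segs <- c(segs, list(render_constituent(cons[[k]], nf)))
    labs <- c(labs, cons[[k]]$subevent_label)
  }
  lens <- vapply(segs, nrow, integer(1))
  ends <- cumsum(lens)
  list(features = do.call(rbind, segs),
       subevents = data.frame(label = labs, start = ends - lens, end = ends,
                              stringsAsFactors = FALSE),
       first_pose = cons[[1L]]$key_pose,
       last_pose = cons[[length(cons)]]$key_pose)
}

#' Add observation noise
#'
#' I.i.d. Gaussian noise of standard deviation `sigma` added to every entry,
#' the final generation step; labels are untouched.
#'
#' @param x Numeric feature matrix.
#' @param sigma Noise standard deviation (`>= 0`).
#' @return Matrix of the same shape.
#' @export
add_observation_noise <- function(x, sigma) {
  if (sigma < 0) stop("sigma must be >= 0")
  if (sigma == 0) return(x)
  x + matrix(stats::rnorm(length(x), 0, sigma), nrow = nrow(x))
}

# Derive stream sub-seeds from one master seed so that the event sequence,
# the event rendering and the observation noise use separate, reproducible
# generator streams.
derive_seeds <- function(seed, n = 3L) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

#' Generate a labeled behavioral time-series
#'
#' Composes the full pipeline: sample an event-label sequence, realize each
#' event, join consecutive events with pose-transition segments of 2-8
#' samples carrying the transition label, then add observation noise. The
#' same `(spec, n_events, seed)` always yields bit-identical output; one
#' master seed drives separate generator streams for the sequence, the
#' rendering and the noise.
#'
#' @param spec A valid [ethogram_spec].
#' @param n_events Number of behavior events to generate.
#' @param seed Integer master seed.
#' @param merge_transitions If `TRUE`, inter-event transition samples are
#'   relabeled with the following event's behavior label, mimicking
#'   annotation conventions that absorb transitions; sub-event labels keep
#'   the transition tag. Default keeps the transition label.
#' @return An object of class `ethogram_series` with fields `features`
#'   (time by `F` matrix), `behavior` and `subevent` (per-sample labels),
#'   `events` and `subevents` (0-based half-open tables), `seed`,
#'   `spec_name` and the generating `spec`.
#' @export
generate_dataset <- function(spec, n_events, seed,
                             merge_transitions = FALSE) {
  diags <- validate_spec(spec)
  if (length(diags)) stop("invalid spec: ", paste(diags, collapse = "; "))
  seeds <- derive_seeds(seed, 3L)
  set.seed(seeds[1L])
  labs <- sample_event_sequence(spec, n_events)

  set.seed(seeds[2L])
  tr <- spec$transition_range
  feat <- vector("list", 2L * n_events - 1L)
  beh <- vector("list", 2L * n_events - 1L)
  sub <- vector("list", 2L * n_events - 1L)
  ev_start <- integer(n_events); ev_end <- integer(n_events)
  sub_tabs <- vector("list", n_events)
  pos <- 0L
  last_pose <- NULL
  for (i in seq_len(n_events)) {
    ev <- realize_event(spec$behaviors[[labs[i]]], spec)
    if (i > 1L) {
      len <- sample.int(tr[2] - tr[1] + 1L, 1L) + tr[1] - 1L
      tseg <- make_transition(last_pose$mean, ev$first_pose$mean, len,
                              scatter = (last_pose$spread +
                                         ev$first_pose$spread) / 4,
                              range = tr)
      feat[[2L * i - 2L]] <- tseg
      beh[[2L * i - 2L]] <- rep.int(spec$transition_label, len)
      sub[[2L * i - 2L]] <- rep.int(spec$transition_label, len)
      pos <- pos + len
    }
    n_ev <- nrow(ev$features)
    feat[[2L * i - 1L]] <- ev$features
    beh[[2L * i - 1L]] <- rep.int(labs[i], n_ev)
    sub[[2L * i - 1L]] <- rep.int(ev$subevents$label, ev$subevents$end -
                                    ev$subevents$start)
    ev_start[i] <- pos; ev_end[i] <- pos + n_ev
    st <- ev$subevents
    st$start <- st$start + pos; st$end <- st$end + pos
    st$event <- i
    sub_tabs[[i]] <- st
    pos <- pos + n_ev
    last_pose <- ev$last_pose
  }
  features <- do.call(rbind, feat)
  behavior <- unlist(beh, use.names = FALSE)
  subevent <- unlist(sub, use.names = FALSE)
  events <- data.frame(event = seq_len(n_events), label = labs,
                       start = ev_start, end = ev_end,
                       stringsAsFactors = FALSE)
  subevents <- do.call(rbind, sub_tabs)
  subevents <- subevents[, c("event", "label", "start", "end")]
  rownames(subevents) <- NULL

  set.seed(seeds[3L])
  features <- add_observation_noise(features, spec$noise_sigma)
  colnames(features) <- paste0("f", seq_len(spec$n_features))

  if (merge_transitions) {
    is_tr <- behavior == spec$transition_label
    nxt <- character(length(behavior))
    cur <- NA_character_
    for (i in rev(seq_along(behavior))) {
      if (!is_tr[i]) cur <- behavior[i]
      nxt[i] <- cur
    }
    behavior[is_tr] <- nxt[is_tr]
  }

  structure(list(features = features, behavior = behavior,
                 subevent = subevent, events = events, subevents = subevents,
                 seed = as.integer(seed), spec_name = spec$name, spec = spec,
                 merge_transitions = merge_transitions),
            class = "ethogram_series")
}

#' @export
print.ethogram_series <- function(x, ...) {
  cat("Ethogram series '", x$spec_name, "': ", nrow(x$features),
      " samples x ", ncol(x$features), " features, ",
      nrow(x$events), " events, seed ", x$seed, "\n", sep = "")
  tab <- sort(table(x$behavior), decreasing = TRUE)
  cat("  samples per label: ",
      paste(names(tab), tab, sep = "=", collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @export
summary.ethogram_series <- function(object, ...) {
  durs <- object$events$end - object$events$start
  by_lab <- tapply(durs, object$events$label, mean)
  out <- list(n_samples = nrow(object$features),
              n_events = nrow(object$events),
              mean_event_duration = by_lab,
              samples_per_label = table(object$behavior))
  class(out) <- "summary.ethogram_series"
  out
}

#' @export
print.summary.ethogram_series <- function(x, ...) {
  cat("Samples:", x$n_samples, " Events:", x$n_events, "\n")
  cat("Mean event duration (samples):\n")
  print(round(x$mean_event_duration, 1))
  invisible(x)
}

#' @export
plot.ethogram_series <- function(x, from = 1L, to = min(nrow(x$features), 600L),
                                 feature = 1L, ...) {
  idx <- from:to
  labs <- sort(unique(x$behavior))
  cols <- grDevices::hcl.colors(length(labs), "Dark 3")
  graphics::plot(idx - 1L, x$features[idx, feature], type = "l",
                 col = "grey40", xlab = "sample", ylab = "feature", ...)
  graphics::points(idx - 1L, x$features[idx, feature], pch = 16, cex = 0.4,
                   col = cols[match(x$behavior[idx], labs)])
  graphics::legend("topright", legend = labs, col = cols, pch = 16,
                   cex = 0.6, ncol = 2)
  invisible(x)
}

# ---------------------------------------------------------------------------
# Tabular I/O: CSV of samples + JSON sidecar with events and metadata.

#' Write and read generated series
#'
#' The sample table is written as CSV with one row per sample: 0-based time
#' index, `F` feature columns, behavior label and sub-event label. Events,
#' sub-events, seed, spec name and the full generating spec go to a JSON
#' sidecar (`<path>.meta.json`). `read_series()` restores an equal
#' `ethogram_series`.
#'
#' @param series An `ethogram_series`.
#' @param path CSV file path; the sidecar lives next to it.
#' @return `write_series()` returns `path` invisibly; `read_series()` the
#'   restored series.
#' @export
write_series <- function(series, path) {
  nf <- ncol(series$features)
  df <- data.frame(time = seq_len(nrow(series$features)) - 1L)
  for (j in seq_len(nf))
    df[[paste0("f", j)]] <- sprintf("%.17g", series$features[, j])
  df$behavior <- series$behavior
  df$subevent <- series$subevent
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  meta <- list(seed = series$seed, spec_name = series$spec_name,
               merge_transitions = series$merge_transitions,
               events = series$events, subevents = series$subevents,
               spec = spec_to_list(series$spec))
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE,
                       digits = NA, null = "null", dataframe = "columns")
  invisible(path)
}

#' @rdname write_series
#' @export
read_series <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("time", "behavior", "subevent")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("malformed series file '", path, "': missing column(s) ",
         paste(miss, collapse = ", "))
  fcols <- grep("^f[0-9]+$", names(df), value = TRUE)
  if (length(fcols) == 0L)
    stop("malformed series file '", path, "': no feature columns")
  for (fc in fcols) {
    bad <- which(!is.finite(suppressWarnings(as.numeric(df[[fc]]))))
    if (length(bad))
      stop("malformed series file '", path, "': non-numeric value in column ",
           fc, " at line ", bad[1L] + 1L)
  }
  features <- as.matrix(df[, fcols, drop = FALSE])
  storage.mode(features) <- "double"
  rownames(features) <- NULL
  mpath <- paste0(path, ".meta.json")
  if (!file.exists(mpath)) stop("missing sidecar metadata: ", mpath)
  meta <- jsonlite::read_json(mpath, simplifyVector = TRUE,
                              simplifyDataFrame = TRUE)
  spec <- list_to_spec(jsonlite::read_json(mpath, simplifyVector = TRUE,
                                           simplifyDataFrame = FALSE,
                                           simplifyMatrix = FALSE)$spec)
  structure(list(features = features, behavior = df$behavior,
                 subevent = df$subevent,
                 events = as.data.frame(meta$events),
                 subevents = as.data.frame(meta$subevents),
                 seed = as.integer(meta$seed), spec_name = meta$spec_name,
                 spec = spec, merge_transitions = meta$merge_transitions),
            class = "ethogram_series")
}
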