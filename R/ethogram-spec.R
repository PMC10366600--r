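# Domain types for the hierarchical behavior model: key poses, duration
# distributions, within-event fluctuations, constituents (state/point events),
# behavior definitions (atomic, ordered, unordered) and the full ethogram spec.

#' Define a key pose
#'
#' A key pose is a characteristic body posture, represented as a distribution
#' in abstract feature space: a per-feature location and a strictly positive
#' per-feature scale. Samples belonging to a state or point event scatter
#' around the pose location with this scale.
#'
#' @param id Short identifier, unique within a spec.
#' @param mean Numeric vector of per-feature locations (length `F`).
#' @param spread Numeric vector of per-feature scales, all `> 0`. Recycled to
#'   the length of `mean`.
#' @param held_frac Fraction of the scatter *variance* held fixed over one
#'   execution of the pose (in `[0, 1)`). A key pose is a posture the animal
#'   holds: most of the execution-to-execution variation is a per-execution
#'   offset, the rest per-sample jitter. The single-sample marginal is
#'   `N(mean, spread)` either way.
#' @return An object of class `key_pose`.
#' @export
key_pose <- function(id, mean, spread, held_frac = 0.8) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  mean <- as.numeric(mean)
  spread <- rep_len(as.numeric(spread), length(mean))
  if (!all(is.finite(mean))) stop("key pose '", id, "': mean must be finite")
  if (!all(spread > 0)) stop("key pose '", id, "': spread must be > 0")
  if (held_frac < 0 || held_frac >= 1)
    stop("key pose '", id, "': held_frac must be in [0, 1)")
  structure(list(id = id, mean = mean, spread = spread,
                 held_frac = held_frac), class = "key_pose")
}

#' Duration distributions for event constituents
#'
#' Durations are integer sample counts drawn from one of three families:
#' `fixed` (a constant), `uniform-int` (discrete uniform over an integer
#' range) and `gamma-rounded` (a gamma variate rounded to the nearest
#' integer). All families clamp at `minimum`.
#'
#' @param n Fixed duration in samples.
#' @param min,max Integer bounds of the uniform family.
#' @param mean Mean of the gamma family (samples).
#' @param shape Gamma shape parameter; the scale is `mean / shape`.
#' @param minimum Smallest admissible duration (samples, `>= 1`).
#' @return An object of class `duration_dist`.
#' @name duration_dist
NULL

new_duration_dist <- function(family, params, minimum) {
  minimum <- as.integer(minimum)
  stopifnot(minimum >= 1L, all(unlist(params) > 0))
  structure(list(family = family, params = params, minimum = minimum),
            class = "duration_dist")
}

#' @rdname duration_dist
#' @export
dur_fixed <- function(n) new_duration_dist("fixed", list(n = as.integer(n)), n)

#' @rdname duration_dist
#' @export
dur_unif <- function(min, max) {
  stopifnot(min <= max)
  new_duration_dist("uniform-int",
                    list(min = as.integer(min), max = as.integer(max)), min)
}

#' @rdname duration_dist
#' @export
dur_gamma <- function(mean, shape = 4, minimum = 2) {
  stopifnot(mean > 0, shape > 0)
  new_duration_dist("gamma-rounded", list(mean = mean, shape = shape), minimum)
}

#' Draw integer durations from a duration distribution
#'
#' @param dd A [duration_dist] object.
#' @param n Number of draws.
#' @return Integer vector of durations, all `>= dd$minimum`.
#' @export
sample_duration <- function(dd, n = 1L) {
  stopifnot(inherits(dd, "duration_dist"))
  x <- switch(dd$family,
    "fixed"         = rep.int(dd$params$n, n),
    "uniform-int"   = sample.int(dd$params$max - dd$params$min + 1L, n,
                                 replace = TRUE) + dd$params$min - 1L,
    "gamma-rounded" = as.integer(round(stats::rgamma(
                        n, shape = dd$params$shape,
                        scale = dd$params$mean / dd$params$shape))),
    stop("unknown duration family: ", dd$family))
  pmax(as.integer(x), dd$minimum)
}

duration_mean <- function(dd) {
  switch(dd$family,
    "fixed"         = dd$params$n,
    "uniform-int"   = (dd$params$min + dd$params$max) / 2,
    "gamma-rounded" = max(dd$params$mean, dd$minimum))
}

#' Within-event fluctuation specification
#'
#' Fluctuations are additive perturbations applied per event on top of the
#' key-pose scatter: a smoothed Gaussian wander (standard deviation `amount`,
#' low-passed by a moving average of `smoothness` samples) and, optionally, a
#' sinusoid of the given `period` and `period_amplitude` with a random phase
#' per event.
#'
#' @param amount Standard deviation of the wander (feature units, `>= 0`).
#' @param smoothness Moving-average window in samples (`>= 1`).
#' @param period Sinusoid period in samples (`>= 2`), or `NULL` for none.
#' @param period_amplitude Sinusoid amplitude (feature units, `>= 0`).
#' @return An object of class `fluctuation_spec`.
#' @export
fluctuation <- function(amount = 0, smoothness = 1, period = NULL,
                        period_amplitude = 0) {
  stopifnot(amount >= 0, smoothness >= 1, period_amplitude >= 0)
  if (!is.null(period)) stopifnot(period >= 2)
  if (is.null(period) != (period_amplitude == 0))
    stop("period must be present iff period_amplitude > 0")
  structure(list(amount = amount, smoothness = as.integer(smoothness),
                 period = period, period_amplitude = period_amplitude),
            class = "fluctuation_spec")
}

#' Event constituents: state and point events
#'
#' A constituent is one sub-unit of a behavior: a `state` event holds a key
#' pose with variation over a sampled duration (`>= 2` samples); a `point`
#' event is a momentary key pose lasting exactly one sample.
#'
#' @param key_pose A [key_pose] object.
#' @param duration A [duration_dist] with `minimum >= 2` (states only).
#' @param fluct A [fluctuation_spec] (states only; points have none).
#' @param subevent_label Short sub-event label; behavior constructors qualify
#'   it with the behavior label.
#' @return An object of class `constituent`.
#' @name constituent
NULL

new_constituent <- function(kind, key_pose, duration, fluct, subevent_label) {
  stopifnot(kind %in% c("state", "point"), inherits(key_pose, "key_pose"),
            inherits(duration, "duration_dist"),
            inherits(fluct, "fluctuation_spec"))
  if (kind == "point" &&
      !(duration$family == "fixed" && duration$params$n == 1L))
    stop("point constituents have fixed duration 1")
  if (kind == "state" && duration$minimum < 2L)
    stop("state constituents need duration minimum >= 2")
  structure(list(kind = kind, key_pose = key_pose, duration = duration,
                 fluctuation = fluct, subevent_label = subevent_label),
            class = "constituent")
}

#' @rdname constituent
#' @export
state_constituent <- function(key_pose, duration = dur_gamma(20),
                              fluct = fluctuation(), subevent_label = "s") {
  new_constituent("state", key_pose, duration, fluct, subevent_label)
}

#' @rdname constituent
#' @export
point_constituent <- function(key_pose, subevent_label = "p") {
  new_constituent("point", key_pose, dur_fixed(1), fluctuation(),
                  subevent_label)
}

qualify_sub <- function(label, constituents) {
  lapply(constituents, function(cn) {
    if (!grepl(".", cn$subevent_label, fixed = TRUE))
      cn$subevent_label <- paste(label, cn$subevent_label, sep = ".")
    cn
  })
}

#' Behavior definitions
#'
#' A behavior is either atomic (a single state or point constituent), an
#' ordered sequence of constituents executed left to right with internal pose
#' transitions in between, or an unordered set of constituents from which a
#' sampled number of repeats is drawn (with optional mixture weights).
#'
#' @param label Short behavior label (e.g., `"b13"`), unique within a spec.
#' @param constituent A single [constituent] (atomic form).
#' @param constituents List of `>= 2` [constituent]s (ordered/unordered).
#' @param repeat_count A [duration_dist] for the number of repeats drawn per
#'   event (unordered form).
#' @param mixture_weights Optional per-constituent selection probabilities
#'   summing to 1 (unordered form); uniform when `NULL`.
#' @return An object of class `behavior_def`.
#' @name behavior_def
NULL

new_behavior <- function(label, structure_type, constituents,
                         repeat_count = NULL, mixture_weights = NULL) {
  structure(list(label = label, structure_type = structure_type,
                 constituents = qualify_sub(label, constituents),
                 repeat_count = repeat_count,
                 mixture_weights = mixture_weights),
            class = "behavior_def")
}

#' @rdname behavior_def
#' @export
behavior_atomic <- function(label, constituent) {
  stopifnot(inherits(constituent, "constituent"))
  new_behavior(label, "atomic", list(constituent))
}

#' @rdname behavior_def
#' @export
behavior_ordered <- function(label, constituents) {
  stopifnot(length(constituents) >= 2L)
  new_behavior(label, "ordered", constituents)
}

#' @rdname behavior_def
#' @export
behavior_unordered <- function(label, constituents, repeat_count,
                               mixture_weights = NULL) {
  stopifnot(length(constituents) >= 2L, inherits(repeat_count, "duration_dist"))
  if (!is.null(mixture_weights)) {
    stopifnot(length(mixture_weights) == length(constituents),
              all(mixture_weights >= 0),
              abs(sum(mixture_weights) - 1) < 1e-8)
  }
  new_behavior(label, "unordered", constituents, repeat_count, mixture_weights)
}

#' Assemble an ethogram specification
#'
#' The full generative definition of a behavior repertoire: the behaviors,
#' the feature dimensionality, the admissible range of pose-transition
#' lengths inserted between events (and between constituents of composite
#' behaviors), the observation-noise level and the label carried by
#' transition samples.
#'
#' @param behaviors List of [behavior_def] objects with unique labels.
#' @param n_features Feature dimensionality `F` (integer `>= 1`).
#' @param transition_range Integer `[min, max]` transition length in samples;
#'   default `c(2, 8)` with `min >= 2`.
#' @param noise_sigma Observation-noise standard deviation (feature units).
#' @param transition_label Label assigned to inter-event transition samples.
#' @param name Spec name used in metadata.
#' @param groups Optional named list of confusion groups (character vectors of
#'   member behavior labels).
#' @return An object of class `ethogram_spec`.
#' @seealso [make_state_preset()], [make_composite_preset()], [validate_spec()]
#' @export
ethogram_spec <- function(behaviors, n_features = 1L,
                          transition_range = c(2L, 8L), noise_sigma = 0.05,
                          transition_label = "b00", name = "custom",
                          groups = list()) {
  labels <- vapply(behaviors, function(b) b$label, character(1))
  names(behaviors) <- labels
  structure(list(behaviors = behaviors, n_features = as.integer(n_features),
                 transition_range = as.integer(transition_range),
                 noise_sigma = noise_sigma,
                 transition_label = transition_label, name = name,
                 groups = groups),
            class = "ethogram_spec")
}

#' @export
print.ethogram_spec <- function(x, ...) {
  cat("Ethogram spec '", x$name, "': ", length(x$behaviors),
      " behaviors, F = ", x$n_features, "\n", sep = "")
  for (b in x$behaviors) {
    cat("  ", b$label, " [", b$structure_type, "] ",
        paste(vapply(b$constituents, function(cn)
          paste0(cn$kind, ":", cn$key_pose$id), character(1)),
          collapse = ", "), "\n", sep = "")
  }
  cat("  transitions '", x$transition_label, "' of ",
      x$transition_range[1], "-", x$transition_range[2],
      " samples; noise sigma = ", x$noise_sigma, "\n", sep = "")
  invisible(x)
}

#' List the behavior labels of a spec
#'
#' @param spec An [ethogram_spec].
#' @param transitions Include the transition label as the first entry?
#' @return Character vector of labels.
#' @export
spec_labels <- function(spec, transitions = TRUE) {
  lb <- names(spec$behaviors)
  if (transitions) c(spec$transition_label, lb) else lb
}

#' Confusion groups attached to a spec
#'
#' @param spec An [ethogram_spec].
#' @return Named list of character vectors of member behavior labels.
#' @export
confusion_groups <- function(spec) spec$groups

# ---------------------------------------------------------------------------
# Presets

#' Preset ethogram: state behaviors
#'
#' A one-feature repertoire of ten atomic state behaviors `b01`-`b10` built to
#' probe specific recognition failure modes, with pose transitions labeled
#' `b00`:
#' \itemize{
#'   \item `b01`, `b02`: well-separated poses (sanity classes).
#'   \item `b03`, `b04`: near-identical poses (confusion group 1); their
#'     single-sample Bayes error exceeds 25\%.
#'   \item `b05`: an unordered mixture alternating between two sub-poses.
#'   \item `b06`, `b07`: one shared pose with long (mean ~100 samples) versus
#'     short (mean ~3) event durations (confusion group 2) -- duration is the
#'     sole separating cue.
#'   \item `b08`, `b09`, `b10`: one shared pose; `b08` and `b09` carry
#'     sinusoidal fluctuation with periods 6 and 12 samples, `b10` is
#'     aperiodic (confusion group 3) -- periodicity is the sole cue.
#' }
#' @return A validated [ethogram_spec].
#' @export
make_state_preset <- function() {
  fl <- function(period = NULL, amp = 0)
    fluctuation(amount = 0.1, smoothness = 5, period = period,
                period_amplitude = amp)
  st <- function(label, pose, duration = dur_gamma(20), fluct = fl())
    behavior_atomic(label, state_constituent(pose, duration, fluct))
  pose_b0607 <- key_pose("pose_shared_dur", 2.2, 0.25)
  pose_b0810 <- key_pose("pose_shared_per", -0.5, 0.25)
  behaviors <- list(
    st("b01", key_pose("pose_low", -3.6, 0.25)),
    st("b02", key_pose("pose_high", 3.6, 0.25)),
    st("b03", key_pose("pose_alike_a", 0.7, 0.30)),
    st("b04", key_pose("pose_alike_b", 1.0, 0.30)),
    behavior_unordered("b05",
      list(state_constituent(key_pose("pose_mix_a", -2.2, 0.25),
                             dur_gamma(10), fl(), "m1"),
           state_constituent(key_pose("pose_mix_b", -1.6, 0.25),
                             dur_gamma(10), fl(), "m2")),
      repeat_count = dur_unif(2, 4), mixture_weights = c(0.5, 0.5)),
    st("b06", pose_b0607, dur_gamma(150)),
    st("b07", pose_b0607, dur_gamma(12, shape = 12)),
    st("b08", pose_b0810, fluct = fl(period = 6, amp = 0.5)),
    st("b09", pose_b0810, fluct = fl(period = 12, amp = 0.5)),
    st("b10", pose_b0810)
  )
  ethogram_spec(behaviors, n_features = 1L, noise_sigma = 0.05,
                name = "state",
                groups = list(group1 = c("b03", "b04"),
                              group2 = c("b06", "b07"),
                              group3 = c("b08", "b09", "b10")))
}

#' Preset ethogram: composite behaviors
#'
#' A one-feature repertoire mixing plain states with hierarchically
#' structured behaviors, with pose transitions labeled `b00`:
#' \itemize{
#'   \item `b01`, `b02`: well-separated state behaviors (sanity classes).
#'   \item `b11`: a point behavior (single one-sample key pose) whose pose
#'     overlaps the state behavior `b12`.
#'   \item `b12`: a plain state behavior ("sniff"-like).
#'   \item `b13`: an unordered repeat sequence over sub-poses A, B and X,
#'     where X is the very key pose that defines `b14` and also overlaps
#'     `b12` (confusion group 4).
#'   \item `b14`: an "eat"-like behavior executed as one draw from three
#'     poses (at-feeder overlapping `b12`, sitting, or the shared pose X).
#'   \item `b15`: an ordered point-state-point triple (take-off, stretched
#'     pose, landing), a "jump".
#'   \item `b16`: an ordered state-state-state triple P-X-Q ("walk") whose
#'     middle constituent shares the stretched pose with `b15`
#'     (confusion group 5).
#' }
#' @return A validated [ethogram_spec].
#' @export
make_composite_preset <- function() {
  fl <- function() fluctuation(amount = 0.1, smoothness = 5)
  st <- function(label, pose, duration = dur_gamma(20))
    behavior_atomic(label, state_constituent(pose, duration, fl()))
  pose_groom_x <- key_pose("pose_groom_x", 1.3, 0.25)   # shared b13/b14
  pose_stretch <- key_pose("pose_stretch", -0.2, 0.25)  # shared b15/b16
  behaviors <- list(
    st("b01", key_pose("pose_low", -3.4, 0.25)),
    st("b02", key_pose("pose_high", 3.4, 0.25)),
    behavior_atomic("b11",
      point_constituent(key_pose("pose_rear", 1.1, 0.25))),
    st("b12", key_pose("pose_sniff", 0.9, 0.25)),
    behavior_unordered("b13",
      list(state_constituent(key_pose("pose_groom_a", -1.5, 0.25),
                             dur_gamma(10), fl(), "A"),
           state_constituent(key_pose("pose_groom_b", -0.9, 0.25),
                             dur_gamma(10), fl(), "B"),
           state_constituent(pose_groom_x, dur_gamma(22, shape = 16),
                             fl(), "X")),
      repeat_count = dur_unif(2, 4),
      mixture_weights = c(1, 1, 1) / 3),
    behavior_unordered("b14",
      list(state_constituent(key_pose("pose_eat_feeder", 1.0, 0.25),
                             dur_gamma(20), fl(), "feeder"),
           state_constituent(key_pose("pose_eat_sit", 0.5, 0.25),
                             dur_gamma(20), fl(), "sit"),
           state_constituent(pose_groom_x, dur_gamma(20), fl(), "X")),
      repeat_count = dur_fixed(1),
      mixture_weights = c(1, 1, 1) / 3),
    behavior_ordered("b15",
      list(point_constituent(key_pose("pose_takeoff", 2.0, 0.25), "takeoff"),
           state_constituent(pose_stretch, dur_gamma(12), fl(), "X"),
           point_constituent(key_pose("pose_landing", 2.4, 0.25), "landing"))),
    behavior_ordered("b16",
      list(state_constituent(key_pose("pose_walk_p", -2.3, 0.25),
                             dur_gamma(8), fl(), "P"),
           state_constituent(pose_stretch, dur_gamma(12), fl(), "X"),
           state_constituent(key_pose("pose_walk_q", 1.7, 0.25),
                             dur_gamma(8), fl(), "Q")))
  )
  ethogram_spec(behaviors, n_features = 1L, noise_sigma = 0.05,
                name = "composite",
                groups = list(group4 = c("b13", "b14"),
                              group5 = c("b15", "b16")))
}

# ---------------------------------------------------------------------------
# Validation

#' Validate an ethogram spec
#'
#' Checks every type invariant (positive spreads, duration minima, point
#' durations, label uniqueness, transition-range bounds, mixture weights,
#' feature-dimension consistency) and returns diagnostics rather than
#' raising.
#'
#' @param spec An [ethogram_spec].
#' @return Character vector of diagnostics; `character(0)` when valid. Each
#'   entry names the offending behavior or field.
#' @export
validate_spec <- function(spec) {
  diags <- character(0)
  note <- function(...) diags <<- c(diags, paste0(...))
  if (!inherits(spec, "ethogram_spec")) return("not an ethogram_spec")
  tr <- spec$transition_range
  if (length(tr) != 2L || tr[1] < 2L || tr[1] > tr[2])
    note("transition_range: must satisfy 2 <= min <= max, got [",
         paste(tr, collapse = ", "), "]")
  if (spec$n_features < 1L) note("n_features: must be >= 1")
  if (!is.numeric(spec$noise_sigma) || spec$noise_sigma < 0)
    note("noise_sigma: must be >= 0")
  labels <- vapply(spec$behaviors, function(b) b$label, character(1))
  dup <- unique(labels[duplicated(labels)])
  for (d in dup) note("behavior label '", d, "': duplicated")
  if (spec$transition_label %in% labels)
    note("transition_label '", spec$transition_label,
         "': collides with a behavior label")
  for (b in spec$behaviors) {
    if (b$structure_type == "ordered" && length(b$constituents) < 2L)
      note(b$label, ": ordered structure needs >= 2 constituents")
    if (b$structure_type == "unordered") {
      if (length(b$constituents) < 2L)
        note(b$label, ": unordered structure needs >= 2 constituents")
      if (is.null(b$repeat_count))
        note(b$label, ": unordered structure needs a repeat_count")
      w <- b$mixture_weights
      if (!is.null(w) && (length(w) != length(b$constituents) ||
                          abs(sum(w) - 1) > 1e-8))
        note(b$label, ": mixture_weights must match constituents and sum to 1")
    }
    for (cn in b$constituents) {
      kp <- cn$key_pose
      if (length(kp$mean) != spec$n_features)
        note(b$label, "/", kp$id, ": key-pose dimension ", length(kp$mean),
             " != F = ", spec$n_features)
      if (!all(kp$spread > 0)) note(b$label, "/", kp$id, ": spread must be > 0")
      if (!all(is.finite(kp$mean)))
        note(b$label, "/", kp$id, ": mean must be finite")
      if (cn$kind == "point" &&
          !(cn$duration$family == "fixed" && cn$duration$params$n == 1L))
        note(b$label, "/", cn$subevent_label,
             ": point constituents must have fixed duration 1")
      if (cn$kind == "state" && cn$duration$minimum < 2L)
        note(b$label, "/", cn$subevent_label,
             ": state duration minimum must be >= 2")
      flc <- cn$fluctuation
      if (is.null(flc$period) != (flc$period_amplitude == 0))
        note(b$label, "/", cn$subevent_label,
             ": period must be present iff period_amplitude > 0")
    }
  }
  for (g in names(spec$groups)) {
    miss <- setdiff(spec$groups[[g]], labels)
    if (length(miss))
      note("group ", g, ": unknown members ", paste(miss, collapse = ", "))
  }
  diags
}

# ---------------------------------------------------------------------------
# Serialization (JSON, round-trip safe)

spec_to_list <- function(spec) {
  beh <- lapply(spec$behaviors, function(b) {
    list(label = b$label, structure_type = b$structure_type,
         constituents = lapply(b$constituents, function(cn) {
           list(kind = cn$kind,
                key_pose = list(id = cn$key_pose$id, mean = cn$key_pose$mean,
                                spread = cn$key_pose$spread,
                                held_frac = cn$key_pose$held_frac),
                duration = list(family = cn$duration$family,
                                params = cn$duration$params,
                                minimum = cn$duration$minimum),
                fluctuation = list(
                  amount = cn$fluctuation$amount,
                  smoothness = cn$fluctuation$smoothness,
                  period = cn$fluctuation$period,
                  period_amplitude = cn$fluctuation$period_amplitude),
                subevent_label = cn$subevent_label)
         }),
         repeat_count = if (!is.null(b$repeat_count))
           list(family = b$repeat_count$family, params = b$repeat_count$params,
                minimum = b$repeat_count$minimum),
         mixture_weights = b$mixture_weights)
  })
  list(name = spec$name, n_features = spec$n_features,
       transition_range = spec$transition_range,
       noise_sigma = spec$noise_sigma,
       transition_label = spec$transition_label,
       behaviors = unname(beh), groups = spec$groups)
}

list_to_dd <- function(x) {
  dd <- new_duration_dist(x$family, lapply(x$params, function(p)
    if (x$family == "gamma-rounded") as.numeric(p) else as.integer(p)),
    x$minimum)
  dd
}

list_to_spec <- function(x) {
  beh <- lapply(x$behaviors, function(b) {
    cons <- lapply(b$constituents, function(cn) {
      new_constituent(cn$kind,
        key_pose(cn$key_pose$id, cn$key_pose$mean, cn$key_pose$spread,
                 cn$key_pose$held_frac),
        list_to_dd(cn$duration),
        fluctuation(cn$fluctuation$amount, cn$fluctuation$smoothness,
                    cn$fluctuation$period, cn$fluctuation$period_amplitude),
        cn$subevent_label)
    })
    new_behavior(b$label, b$structure_type, cons,
                 repeat_count = if (!is.null(b$repeat_count))
                   list_to_dd(b$repeat_count),
                 mixture_weights = b$mixture_weights)
  })
  ethogram_spec(beh, n_features = x$n_features,
                transition_range = x$transition_range,
                noise_sigma = x$noise_sigma,
                transition_label = x$transition_label, name = x$name,
                groups = lapply(x$groups, as.character))
}

#' Read and write ethogram specs as JSON
#'
#' Specs serialize to a single JSON document; reading it back yields a spec
#' equal field-by-field to the original.
#'
#' @param spec An [ethogram_spec].
#' @param path File path.
#' @return `read_ethogram()` returns an [ethogram_spec]; `write_ethogram()`
#'   returns `path` invisibly.
#' @export
write_ethogram <- function(spec, path) {
  jsonlite::write_json(spec_to_list(spec), path, auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_ethogram
#' @export
read_ethogram <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE,
                           simplifyDataFrame = FALSE, simplifyMatrix = FALSE)
  list_to_spec(x)
}

#' Fetch a preset ethogram by name
#'
#' @param name `"state"` or `"composite"`.
#' @return An [ethogram_spec].
#' @export
get_preset <- function(name) {
  switch(match.arg(name, c("state", "composite")),
         state = make_state_preset(),
         composite = make_composite_preset())
}
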