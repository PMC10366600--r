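# Per-sample confusion matrices at behavior and sub-event level,
# confusion-group summaries, and the closed-form single-sample Bayes-oracle
# classifier used as the context-free upper-bound reference.

#' Per-sample confusion matrix
#'
#' Counts true-by-predicted label pairs and row-normalizes, so each row with
#' nonzero support is the distribution of predictions for that true label.
#' Labels absent from the truth get zero support and an all-zero row.
#'
#' @param true,pred Character vectors of equal length.
#' @param labels Ordered label set; defaults to the sorted union. Any label
#'   outside this set raises an error.
#' @param level `"behavior"` or `"subevent"` (metadata only).
#' @param row_labels Optional distinct row label set (used by
#'   [subevent_confusion()]); defaults to `labels`.
#' @return An object of class `confusion_report` with fields `row_labels`,
#'   `labels` (columns), `matrix` (row-normalized), `counts`, `support` and
#'   `level`.
#' @export
confusion_report <- function(true, pred, labels = NULL, level = "behavior",
                             row_labels = NULL) {
  stopifnot(length(true) == length(pred))
  if (is.null(labels)) labels <- sort(unique(c(true, pred)))
  if (is.null(row_labels)) row_labels <- labels
  bad <- setdiff(unique(true), row_labels)
  if (length(bad)) stop("unknown true label(s): ", paste(bad, collapse = ", "))
  bad <- setdiff(unique(pred), labels)
  if (length(bad))
    stop("unknown predicted label(s): ", paste(bad, collapse = ", "))
  counts <- table(factor(true, levels = row_labels),
                  factor(pred, levels = labels))
  counts <- matrix(as.integer(counts), nrow = length(row_labels),
                   dimnames = list(true = row_labels, predicted = labels))
  support <- rowSums(counts)
  mat <- counts / ifelse(support > 0, support, 1)
  structure(list(row_labels = row_labels, labels = labels, matrix = mat,
                 counts = counts, support = support, level = level),
            class = "confusion_report")
}

#' @export
print.confusion_report <- function(x, digits = 2, ...) {
  cat("Confusion report (", x$level, " level), ", sum(x$support),
      " samples\n", sep = "")
  print(round(x$matrix, digits))
  invisible(x)
}

#' @export
plot.confusion_report <- function(x, main = paste(x$level, "confusion"), ...) {
  m <- x$matrix[rev(seq_len(nrow(x$matrix))), , drop = FALSE]
  graphics::image(seq_along(x$labels), seq_along(x$row_labels), t(m),
                  col = grDevices::hcl.colors(64, "YlOrRd", rev = TRUE),
                  axes = FALSE, xlab = "predicted", ylab = "true",
                  main = main, zlim = c(0, 1), ...)
  graphics::axis(1, seq_along(x$labels), x$labels, las = 2, cex.axis = 0.7)
  graphics::axis(2, seq_along(x$row_labels), rev(x$row_labels), las = 2,
                 cex.axis = 0.7)
  graphics::box()
  invisible(x)
}

#' Per-class recall
#'
#' @param report A `confusion_report` whose rows and columns share labels.
#' @return Named numeric vector: the diagonal of the row-normalized matrix.
#' @export
recalls <- function(report) {
  common <- intersect(report$row_labels, report$labels)
  stats::setNames(report$matrix[cbind(common, common)], common)
}

#' Bootstrap confidence interval on a class recall
#'
#' Utility only: resamples the true-class samples with replacement.
#'
#' @param true,pred Label vectors.
#' @param label Class of interest.
#' @param B Bootstrap replicates.
#' @param conf Coverage.
#' @return Named numeric: estimate, lower, upper.
#' @export
recall_ci <- function(true, pred, label, B = 1000L, conf = 0.95) {
  hit <- (pred == label)[true == label]
  n <- length(hit)
  if (n == 0L) return(c(estimate = NA_real_, lower = NA_real_,
                        upper = NA_real_))
  boots <- vapply(seq_len(B),
                  function(i) mean(hit[sample.int(n, n, replace = TRUE)]),
                  numeric(1))
  qs <- stats::quantile(boots, c((1 - conf) / 2, 1 - (1 - conf) / 2),
                        names = FALSE)
  c(estimate = mean(hit), lower = qs[1], upper = qs[2])
}

#' Sub-event level confusion
#'
#' Rows are the ground-truth sub-event labels of the series (the
#' constituents of composite behaviors, their internal transitions and the
#' inter-event transition label); columns are the predicted behavior
#' labels. This exposes which constituent of a composite behavior absorbs
#' the confusion.
#'
#' @param series An `ethogram_series` carrying sub-event labels.
#' @param pred Per-sample predicted behavior labels.
#' @return A `confusion_report` with `level = "subevent"`.
#' @export
subevent_confusion <- function(series, pred) {
  stopifnot(inherits(series, "ethogram_series"),
            length(pred) == length(series$subevent))
  confusion_report(series$subevent, pred,
                   labels = spec_labels(series$spec),
                   row_labels = sort(unique(series$subevent)),
                   level = "subevent")
}

#' Within-group confusion mass
#'
#' For each confusion group, summarizes how much of its members' row mass
#' lands on *other* members of the same group: for member row `i`, the mass
#' is the sum over within-group off-diagonal columns. Both the
#' support-weighted mean (`mass`) and the unweighted mean over member rows
#' (`mass_unweighted`) are reported; the unweighted form keeps
#' short-duration members visible when a group mixes very long and very
#' short events.
#'
#' @param report A behavior-level `confusion_report`.
#' @param groups Named list of character vectors of member labels (e.g.,
#'   [confusion_groups()] of a preset).
#' @return A data.frame with one row per group: `group`, `members`, `mass`
#'   (support-weighted, in `[0, 1]`), `mass_unweighted`, `support`.
#' @export
group_report <- function(report, groups) {
  empty <- data.frame(group = character(0), members = character(0),
                      mass = numeric(0), mass_unweighted = numeric(0),
                      support = integer(0))
  if (length(groups) == 0L) return(empty)
  rows <- lapply(names(groups), function(g) {
    members <- intersect(groups[[g]], report$row_labels)
    members <- intersect(members, report$labels)
    if (length(members) < 2L)
      return(data.frame(group = g, members = paste(members, collapse = "+"),
                        mass = NA_real_, mass_unweighted = NA_real_,
                        support = 0L))
    mass_i <- vapply(members, function(m) {
      sum(report$matrix[m, setdiff(members, m)])
    }, numeric(1))
    supp <- report$support[members]
    data.frame(group = g, members = paste(members, collapse = "+"),
               mass = if (sum(supp) > 0) sum(supp * mass_i) / sum(supp)
                      else NA_real_,
               mass_unweighted = mean(mass_i),
               support = sum(supp))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# ---------------------------------------------------------------------------
# Bayes oracle: optimal single-sample classifier from the known generative
# densities. It sees one sample at a time, so it can use neither duration,
# nor periodicity phase/frequency, nor sequence context -- the formal
# "switching states" baseline every windowed model is compared against.

# Marginal mixture components of one behavior: one row per constituent with
# time-share weight w, per-feature location mu, total per-sample scale s
# (pose spread + wander + observation noise) and sinusoid amplitude amp.
behavior_components <- function(behavior, spec) {
  cons <- behavior$constituents
  edur <- vapply(cons, function(cn) duration_mean(cn$duration), numeric(1))
  w <- switch(behavior$structure_type,
    atomic = 1,
    ordered = edur / sum(edur),
    unordered = {
      mw <- behavior$mixture_weights
      if (is.null(mw)) mw <- rep(1 / length(cons), length(cons))
      mw * edur / sum(mw * edur)
    })
  lapply(seq_along(cons), function(k) {
    cn <- cons[[k]]
    list(w = w[k], mu = cn$key_pose$mean,
         s = sqrt(cn$key_pose$spread^2 + cn$fluctuation$amount^2 +
                  spec$noise_sigma^2),
         amp = cn$fluctuation$period_amplitude)
  })
}

# Density of one component at points x (vector, F = 1). A sinusoidal
# fluctuation with uniform random phase is marginalized by midpoint
# quadrature over the phase (spectrally accurate for periodic integrands).
component_density <- function(x, comp, n_phase = 64L) {
  if (comp$amp > 0) {
    th <- 2 * pi * (seq_len(n_phase) - 0.5) / n_phase
    rowMeans(vapply(th, function(t)
      stats::dnorm(x, comp$mu[1L] + comp$amp * sin(t), comp$s[1L]),
      numeric(length(x))))
  } else {
    stats::dnorm(x, comp$mu[1L], comp$s[1L])
  }
}

#' Closed-form Bayes-oracle classifier for an ethogram spec
#'
#' Builds the exact single-sample marginal density of every behavior from
#' the spec's known generative parameters (key-pose scatter, wander,
#' observation noise, phase-marginalized sinusoids; composite and mixture
#' behaviors are marginalized over their constituents by expected time
#' share, internal transitions excluded). The resulting maximum-likelihood
#' classifier is the optimal context-free baseline: it cannot exploit
#' duration, periodicity or sequence structure, so any model beating it on
#' a class must be using temporal context.
#'
#' Supported for one-feature specs with Gaussian pose families (both
#' presets).
#'
#' @param spec An [ethogram_spec] with `n_features = 1`.
#' @return An object of class `bayes_oracle` with `labels` and per-behavior
#'   mixture components; use [predict.bayes_oracle()] and [pair_error()].
#' @export
bayes_oracle <- function(spec) {
  if (spec$n_features != 1L)
    stop("the closed-form oracle supports one-feature specs only")
  comps <- lapply(spec$behaviors, behavior_components, spec = spec)
  structure(list(labels = names(spec$behaviors), comps = comps, spec = spec),
            class = "bayes_oracle")
}

oracle_density <- function(oracle, label, x) {
  comps <- oracle$comps[[label]]
  Reduce(`+`, lapply(comps, function(cp)
    cp$w * component_density(x, cp)))
}

#' Classify samples with the Bayes oracle
#'
#' @param object A [bayes_oracle].
#' @param newdata Numeric vector of samples, a one-column matrix, or an
#'   `ethogram_series`.
#' @param ... Unused.
#' @return Character vector of behavior labels (transition samples are
#'   assigned the most likely behavior; the oracle has no transition model).
#' @export
predict.bayes_oracle <- function(object, newdata, ...) {
  x <- if (inherits(newdata, "ethogram_series")) newdata$features[, 1L]
       else as.numeric(newdata)
  dens <- vapply(object$labels, function(lb) oracle_density(object, lb, x),
                 numeric(length(x)))
  object$labels[max.col(dens, ties.method = "first")]
}

#' Pairwise Bayes error between two behaviors
#'
#' The minimum achievable single-sample misclassification rate for an
#' equal-prior two-class problem, `0.5 * integral of min(f_a, f_b)`.
#' `method = "integration"` evaluates the densities on a fine grid and
#' integrates by the trapezoid rule; `method = "mc"` draws samples from the
#' two marginals and classifies them by likelihood, an independent
#' Monte-Carlo estimate of the same quantity.
#'
#' @param oracle A [bayes_oracle].
#' @param a,b Behavior labels.
#' @param method `"integration"` or `"mc"`.
#' @param n Total Monte-Carlo sample count (split evenly between classes).
#' @param grid_n Grid resolution for integration.
#' @return The Bayes error as a proportion in `[0, 0.5]`.
#' @export
pair_error <- function(oracle, a, b, method = c("integration", "mc"),
                       n = 1e6, grid_n = 8001L) {
  method <- match.arg(method)
  stopifnot(a %in% oracle$labels, b %in% oracle$labels)
  if (method == "integration") {
    lim <- range(unlist(lapply(c(a, b), function(lb)
      vapply(oracle$comps[[lb]], function(cp)
        c(cp$mu[1L] - cp$amp - 8 * cp$s[1L],
          cp$mu[1L] + cp$amp + 8 * cp$s[1L]), numeric(2)))))
    x <- seq(lim[1], lim[2], length.out = grid_n)
    fa <- oracle_density(oracle, a, x)
    fb <- oracle_density(oracle, b, x)
    h <- x[2L] - x[1L]
    m <- pmin(fa, fb)
    0.5 * (sum(m) - (m[1L] + m[grid_n]) / 2) * h
  } else {
    half <- ceiling(n / 2)
    xa <- sample_marginal(oracle, a, half)
    xb <- sample_marginal(oracle, b, half)
    err_a <- mean(oracle_density(oracle, b, xa) > oracle_density(oracle, a, xa))
    err_b <- mean(oracle_density(oracle, a, xb) >= oracle_density(oracle, b, xb))
    (err_a + err_b) / 2
  }
}

# Draw n samples from a behavior's single-sample marginal density.
sample_marginal <- function(oracle, label, n) {
  comps <- oracle$comps[[label]]
  w <- vapply(comps, `[[`, numeric(1), "w")
  idx <- sample.int(length(comps), n, replace = TRUE, prob = w)
  x <- numeric(n)
  for (k in seq_along(comps)) {
    cp <- comps[[k]]
    m <- sum(idx == k)
    if (m == 0L) next
    centre <- cp$mu[1L]
    if (cp$amp > 0)
      centre <- centre + cp$amp * sin(stats::runif(m, 0, 2 * pi))
    x[idx == k] <- stats::rnorm(m, centre, cp$s[1L])
  }
  x
}

#' Table of pairwise Bayes errors
#'
#' @param oracle A [bayes_oracle].
#' @param pairs Optional 2-column character matrix of label pairs; defaults
#'   to all unordered pairs.
#' @return Data.frame `a`, `b`, `bayes_error`.
#' @export
pair_error_table <- function(oracle, pairs = NULL) {
  if (is.null(pairs)) {
    cmb <- utils::combn(oracle$labels, 2L)
    pairs <- t(cmb)
  }
  data.frame(a = pairs[, 1L], b = pairs[, 2L],
             bayes_error = vapply(seq_len(nrow(pairs)), function(i)
               pair_error(oracle, pairs[i, 1L], pairs[i, 2L]), numeric(1)))
}
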