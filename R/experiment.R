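# Orchestration: dataset generation with disjoint seeds, model training,
# random-search hyperparameter tuning, evaluation and report bundling with
# reproducibility metadata.

#' Configure an experiment
#'
#' @param preset `"state"` or `"composite"` (or an [ethogram_spec]).
#' @param n_events Named vector with `train`, `val`, `test` event counts.
#' @param seeds Named integer vector with distinct `train`, `val`, `test`
#'   generator seeds.
#' @param models `"vae"`, `"transformer"` or `"both"`.
#' @param vae A [vae_config()].
#' @param transformer A [transformer_config()].
#' @param out_dir Output directory for the report bundle, or `NULL` to keep
#'   results in memory only.
#' @return A list of class `experiment_config`.
#' @export
experiment_config <- function(preset = "state",
                              n_events = c(train = 2000L, val = 300L,
                                           test = 200L),
                              seeds = c(train = 11L, val = 12L, test = 13L),
                              models = c("both", "vae", "transformer"),
                              vae = vae_config(),
                              transformer = transformer_config(),
                              out_dir = NULL) {
  models <- match.arg(models)
  stopifnot(all(c("train", "val", "test") %in% names(n_events)),
            all(c("train", "val", "test") %in% names(seeds)))
  if (anyDuplicated(seeds[c("train", "val", "test")]))
    stop("train/val/test seeds must be distinct")
  if (n_events[["train"]] < 50L)
    stop("training splits need n_events >= 50")
  structure(list(preset = preset, n_events = n_events, seeds = seeds,
                 models = models, vae = vae, transformer = transformer,
                 out_dir = out_dir),
            class = "experiment_config")
}

resolve_spec <- function(preset) {
  if (inherits(preset, "ethogram_spec")) preset else get_preset(preset)
}

# Evaluate one model on a test series: behavior- and sub-event-level
# confusion, group summary and per-class recalls.
evaluate_model <- function(model, test, groups) {
  pred <- predict(model, test)
  beh <- confusion_report(test$behavior, pred,
                          labels = spec_labels(test$spec))
  sub <- subevent_confusion(test, pred)
  list(pred = pred, behavior = beh, subevent = sub,
       groups = group_report(beh, groups), recalls = recalls(beh))
}

#' Run a full experiment
#'
#' Generates train/validation/test series with disjoint seeds, trains the
#' selected models, evaluates per-sample confusion at behavior and
#' sub-event level on the test split, compares against the single-sample
#' Bayes oracle, and (when `out_dir` is set) writes the report bundle:
#' confusion matrices and group summaries as CSV, loss curves as CSV, and
#' a JSON manifest with the config hash, seeds and package version. The
#' same config always reproduces the same metrics.
#'
#' @param config An [experiment_config()].
#' @return A list of class `experiment_result` with elements `datasets`
#'   (the three series), `models`, `reports`, `oracle` and `manifest`,
#'   invisibly when written to disk.
#' @export
run_experiment <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  spec <- resolve_spec(config$preset)
  stage <- function(what, expr) {
    tryCatch(expr, error = function(e)
      stop("experiment stage '", what, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  datasets <- stage("generate", list(
    train = generate_dataset(spec, config$n_events[["train"]],
                             config$seeds[["train"]]),
    val = generate_dataset(spec, config$n_events[["val"]],
                           config$seeds[["val"]]),
    test = generate_dataset(spec, config$n_events[["test"]],
                            config$seeds[["test"]])))
  groups <- confusion_groups(spec)
  models <- list(); reports <- list()
  if (config$models %in% c("both", "vae")) {
    models$vae <- stage("train-vae",
                        fit_rnn_vae(datasets$train, config$vae))
    reports$vae <- stage("evaluate-vae",
                         evaluate_model(models$vae, datasets$test, groups))
  }
  if (config$models %in% c("both", "transformer")) {
    models$transformer <- stage("train-transformer",
                                fit_transformer(datasets$train,
                                                config$transformer))
    reports$transformer <- stage("evaluate-transformer",
                                 evaluate_model(models$transformer,
                                                datasets$test, groups))
  }
  oracle <- stage("oracle", {
    orc <- bayes_oracle(spec)
    pred <- predict(orc, datasets$test)
    beh <- confusion_report(datasets$test$behavior, pred,
                            labels = spec_labels(spec))
    list(behavior = beh, recalls = recalls(beh),
         groups = group_report(beh, groups))
  })
  manifest <- list(spec_name = spec$name,
                   n_events = as.list(config$n_events),
                   seeds = as.list(config$seeds), models = config$models,
                   package_version =
                     as.character(utils::packageVersion("ethosim")),
                   r_version = paste(R.version$major, R.version$minor,
                                     sep = "."))
  result <- structure(list(datasets = datasets, models = models,
                           reports = reports, oracle = oracle,
                           manifest = manifest),
                      class = "experiment_result")
  if (!is.null(config$out_dir)) {
    write_bundle(result, config, config$out_dir)
    return(invisible(result))
  }
  result
}

write_bundle <- function(result, config, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  put <- function(name) { files <<- c(files, name); file.path(dir, name) }
  cfg_path <- put("config.json")
  jsonlite::write_json(list(manifest = result$manifest), cfg_path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  for (mn in names(result$reports)) {
    rp <- result$reports[[mn]]
    utils::write.csv(rp$behavior$matrix,
                     put(paste0(mn, "_confusion_behavior.csv")))
    utils::write.csv(rp$subevent$matrix,
                     put(paste0(mn, "_confusion_subevent.csv")))
    utils::write.csv(rp$groups, put(paste0(mn, "_groups.csv")),
                     row.names = FALSE)
    utils::write.csv(result$models[[mn]]$losses,
                     put(paste0(mn, "_losses.csv")), row.names = FALSE)
  }
  utils::write.csv(result$oracle$behavior$matrix,
                   put("oracle_confusion_behavior.csv"))
  manifest <- c(result$manifest,
                list(config_md5 = unname(tools::md5sum(cfg_path)),
                     files = files))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' @export
print.experiment_result <- function(x, ...) {
  cat("Experiment on '", x$manifest$spec_name, "' (",
      paste(names(x$reports), collapse = " + "), ")\n", sep = "")
  for (mn in names(x$reports)) {
    cat("--", mn, "recalls:\n")
    print(round(x$reports[[mn]]$recalls, 2))
  }
  cat("-- oracle recalls:\n")
  print(round(x$oracle$recalls, 2))
  invisible(x)
}

macro_recall <- function(report) {
  r <- recalls(report)
  mean(r[report$support[names(r)] > 0])
}

#' Random-search hyperparameter tuning
#'
#' Seeded random search over the tunable parameters of one model: learning
#' rate (log-uniform in `[1e-4, 1e-2]`), hidden dimensions and embedding
#' size for both models, plus mask ratio (`[0.15, 0.6]`) and slice window
#' (`{3, 5, 7, 9}`) for the Transformer. Each trial trains on the training
#' series and is scored by macro-averaged recall on the validation series
#' (robust to the extreme class imbalance point events cause).
#'
#' @param train,val `ethogram_series` for fitting and scoring.
#' @param model `"vae"` or `"transformer"`.
#' @param budget Number of trials (`>= 1`).
#' @param base Base config whose non-searched fields (epochs, batch sizes)
#'   are kept.
#' @param seed Seed for the sampler.
#' @return A list with `best` (config), `best_score`, and `trials` (a
#'   data.frame of sampled parameters and scores).
#' @export
tune_model <- function(train, val, model = c("vae", "transformer"),
                       budget = 20L, base = NULL, seed = 1L) {
  model <- match.arg(model)
  stopifnot(budget >= 1L)
  set.seed(seed)
  if (is.null(base))
    base <- if (model == "vae") vae_config() else transformer_config()
  trials <- vector("list", budget)
  configs <- vector("list", budget)
  for (i in seq_len(budget)) {
    lr <- 10^stats::runif(1, -4, -2)
    if (model == "vae") {
      h <- sample(c(16L, 32L, 64L, 128L), 1L)
      d <- sample(c(2L, 4L, 6L, 8L, 12L, 16L), 1L)
      cfg <- base
      cfg$lr <- lr; cfg$h_enc <- h; cfg$d <- d
      trials[[i]] <- data.frame(trial = i, lr = lr, hidden = h,
                                embedding = d, mask_ratio = NA_real_,
                                slice_len = NA_integer_)
    } else {
      h <- sample(c(16L, 32L, 48L, 64L, 80L, 96L, 128L), 1L)
      d <- sample(c(16L, 24L, 32L, 48L, 64L), 1L)
      mr <- stats::runif(1, 0.15, 0.6)
      sl <- sample(c(3L, 5L, 7L, 9L), 1L)
      cfg <- base
      cfg$lr <- lr; cfg$ff_hidden <- h; cfg$d_model <- d
      cfg$mask_ratio <- mr; cfg$slice_len <- sl
      trials[[i]] <- data.frame(trial = i, lr = lr, hidden = h,
                                embedding = d, mask_ratio = mr,
                                slice_len = sl)
    }
    cfg$seed <- base$seed + i
    configs[[i]] <- cfg
  }
  scores <- numeric(budget)
  for (i in seq_len(budget)) {
    fit <- if (model == "vae") fit_rnn_vae(train, configs[[i]])
           else fit_transformer(train, configs[[i]])
    pred <- predict(fit, val)
    rep <- confusion_report(val$behavior, pred,
                            labels = spec_labels(val$spec))
    scores[i] <- macro_recall(rep)
  }
  trials <- do.call(rbind, trials)
  trials$score <- scores
  best <- which.max(scores)
  list(best = configs[[best]], best_score = scores[best], trials = trials)
}
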