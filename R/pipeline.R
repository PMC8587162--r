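#' End-to-end model workflows
#'
#' The four regression workflows share one driver: Model 1 maps NIR
#' derivative features to berry vitality (Bayesian regularization, 75/25
#' train/test); Model 2 maps the six canopy-architecture features to berry
#' vitality (Levenberg-Marquardt, 60/20/20); Models 3 and 4 map canopy
#' features to the ten sensory descriptor intensities of Chardonnay and
#' Shiraz respectively (Levenberg-Marquardt, 60/20/20).
#'
#' @name pipeline
NULL

model_defaults <- list(
  `1` = list(algorithm = "bayesian_regularization",
             fractions = c(0.75, 0, 0.25), n_hidden = 3L),
  `2` = list(algorithm = "levenberg_marquardt",
             fractions = c(0.60, 0.20, 0.20), n_hidden = 10L),
  `3` = list(algorithm = "levenberg_marquardt",
             fractions = c(0.60, 0.20, 0.20), n_hidden = 5L),
  `4` = list(algorithm = "levenberg_marquardt",
             fractions = c(0.60, 0.20, 0.20), n_hidden = 3L)
)

#' Run one model workflow
#'
#' Splits the data, optionally sweeps hidden-layer sizes (neuron trimming),
#' trains the network, and assembles per-stage diagnostics plus the
#' 95%-prediction-bound outlier report on the overall fit.
#'
#' @param model_id 1, 2, 3 or 4 (sets algorithm, split and hidden size
#'   defaults; all overridable).
#' @param features numeric matrix/data.frame of inputs.
#' @param targets numeric matrix/data.frame of targets.
#' @param seed integer seed used for the split and weight initialization.
#' @param n_hidden hidden-layer size; default per model.
#' @param trim if `TRUE`, run [neuron_trimming()] over `candidates` and use
#'   the selected size.
#' @param candidates trimming candidates (default `c(3, 5, 7, 10)`).
#' @param max_epochs training epoch cap (default 300).
#' @return object of class `model_report`: list with `model_id`, `fit`
#'   (`ann_fit`), `diagnostics` tibble (stages x `n_samples`,
#'   `n_observations`, `r`, `slope`, `mse`), `outliers`
#'   (`outlier_report`), `trimming` (`trimming_report` or `NULL`), `seed`.
#' @export
run_model <- function(model_id, features, targets, seed = 1L,
                      n_hidden = NULL, trim = FALSE,
                      candidates = c(3L, 5L, 7L, 10L), max_epochs = 300L) {
  key <- as.character(model_id)
  if (!key %in% names(model_defaults)) stop("model_id must be 1, 2, 3 or 4")
  defs <- model_defaults[[key]]
  X <- as.matrix(features); Y <- as.matrix(targets)
  if (nrow(X) != nrow(Y)) stop("features and targets have different row counts")
  if (anyNA(X) || anyNA(Y)) stop("missing values in features or targets")
  split <- split_dataset(nrow(X), defs$fractions, seed = seed)
  cfg <- network_config(
    n_inputs = ncol(X),
    n_hidden = if (is.null(n_hidden)) defs$n_hidden else n_hidden,
    n_outputs = ncol(Y),
    algorithm = defs$algorithm,
    max_epochs = max_epochs,
    seed = seed
  )
  trimming <- NULL
  if (trim) {
    trimming <- neuron_trimming(X, Y, split, cfg, candidates = candidates)
    cfg$n_hidden <- trimming$selected
    fit <- trimming$fits[[as.character(trimming$selected)]]
  } else {
    fit <- train_network(X, Y, split, cfg)
  }
  pred <- predict(fit$network, X)
  outliers <- prediction_bound_outliers(pred, Y, level = 0.95)
  structure(
    list(model_id = model_id, fit = fit, diagnostics = fit$diagnostics,
         outliers = outliers, trimming = trimming, seed = seed,
         config = cfg),
    class = "model_report"
  )
}

#' Write a model report to disk
#'
#' Per-stage diagnostics as CSV (the layout of the accuracy tables:
#' stage, samples, observations, R, slope, MSE), the outlier report and
#' configuration as JSON, and the trained network as JSON.
#'
#' @param report a `model_report` from [run_model()].
#' @param dir output directory (created if missing).
#' @return invisibly, the directory.
#' @export
write_model_report <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  prefix <- file.path(dir, sprintf("model%s", report$model_id))
  utils::write.csv(report$diagnostics, paste0(prefix, "_diagnostics.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(model_id = report$model_id, seed = report$seed,
         algorithm = report$config$algorithm,
         n_hidden = report$config$n_hidden,
         outliers = unclass(report$outliers),
         trimming = if (!is.null(report$trimming)) {
           as.list(report$trimming$candidates)
         }),
    paste0(prefix, "_report.json"), digits = NA, auto_unbox = TRUE
  )
  network_to_json(report$fit, paste0(prefix, "_network.json"))
  invisible(dir)
}

#' @export
print.model_report <- function(x, ...) {
  cat(sprintf("Model %s (%s, %d hidden neurons)\n", x$model_id,
              x$config$algorithm, x$config$n_hidden))
  print(x$diagnostics)
  cat(sprintf("Outliers outside %.0f%% prediction bounds: %d/%d (%.2f%%)\n",
              100 * x$outliers$level, x$outliers$n_outliers,
              x$outliers$n_total, x$outliers$percent))
  invisible(x)
}

#' Reference group-mean canopy parameters
#'
#' Published per-group means of the canopy-architecture parameters (LAI,
#' canopy cover, crown cover, crown porosity, clumping index) for
#' field-grown Chardonnay and Shiraz, shipped as a plain-text table. Used
#' to check the internal consistency of the canopy equation engine against
#' independently printed values.
#'
#' @return tibble with columns `cultivar`, `group`, `lai`, `fc`, `ff`,
#'   `phi`, `omega`.
#' @export
canopy_reference_means <- function() {
  path <- system.file("extdata", "canopy_group_means.csv", package = "grapevit")
  tibble::as_tibble(utils::read.csv(path))
}
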