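# End-to-end pipeline: generate -> screen -> train (ANN + SVR) -> evaluate ->
# select -> importance, with a written manifest; plus the clinical
# decision-support operations (iterative Gn-dose tailoring and
# ovarian-response risk flags).

#' Pipeline run configuration
#'
#' @param generator an [generator_config()]; default is the packaged cohort
#'   calibration.
#' @param alpha screening significance level.
#' @param split an [split_spec()] for the network training.
#' @param thresholds absolute-error thresholds for the evaluation reports.
#' @param ann named list of [train_ann()] arguments (e.g. `max_iter`).
#' @param svr named list of [train_svr()] arguments.
#' @param seed global seed; stage seeds are derived from it.
#' @return A list of class `ovr_run_config`.
#' @export
run_config <- function(generator = default_generator_config(),
                       alpha = 0.05, split = NULL, thresholds = c(3, 5),
                       ann = list(), svr = list(), seed = 1) {
  seed <- as.integer(seed)
  if (is.null(split)) split <- split_spec(seed = seed + 1L)
  structure(list(generator = generator, alpha = alpha, split = split,
                 thresholds = thresholds, ann = ann, svr = svr, seed = seed),
            class = "ovr_run_config")
}

pipeline_stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full modelling pipeline
#'
#' Executes all stages in order — cohort generation, Pearson screening,
#' training of the neural-network and support-vector regressors on the
#' selected features, evaluation of both (full-cohort and test-only), model
#' selection by RMSE, and perturbation importance for the selected model —
#' and writes every artifact (cohort CSV, screening CSV, two model JSON
#' files, evaluation JSONs, importance CSV) plus a manifest JSON with seeds,
#' package version and MD5 hashes to `out_dir`. Rerunning with the same
#' configuration reproduces byte-identical artifacts. A failed stage aborts
#' with the stage name; artifacts written so far are kept and a `.partial`
#' marker file records the failure point.
#'
#' @param config an [run_config()].
#' @param out_dir output directory (created if needed).
#' @return The manifest, invisibly, as a list (also written to
#'   `manifest.json`).
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "ovr_run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  marker <- file.path(out_dir, ".partial")
  writeLines("pipeline in progress", marker)
  paths <- list()
  wr <- function(name, writer) {
    p <- file.path(out_dir, name)
    writer(p)
    paths[[name]] <<- p
    p
  }

  cohort <- pipeline_stage("generate",
    generate_cohort(config$generator, seed = config$seed))
  wr("cohort.csv", function(p) write_cohort(cohort, p))

  screen <- pipeline_stage("screen", pearson_screen(cohort, config$alpha))
  wr("screening.csv", function(p)
    utils::write.csv(as.data.frame(screen), p, row.names = FALSE))
  feats <- selected_features(screen)
  if (!length(feats)) stop("pipeline stage 'screen' failed: no features selected")

  ann <- pipeline_stage("train_ann", do.call(train_ann, c(
    list(cohort = cohort, features = feats, split = config$split,
         seed = config$seed + 2L), config$ann)))
  svr <- pipeline_stage("train_svr", do.call(train_svr, c(
    list(cohort = cohort, features = feats, seed = config$seed + 3L),
    config$svr)))
  wr("model_ann.json", function(p) write_model(ann, p))
  wr("model_svr.json", function(p) write_model(svr, p))

  reports <- pipeline_stage("evaluate", list(
    ann = evaluate_model(ann, cohort, config$thresholds),
    svr = evaluate_model(svr, cohort, config$thresholds),
    ann_test = evaluate_model(ann, cohort, config$thresholds,
                              scope = "test_only")))
  wr("evaluation.json", function(p) jsonlite::write_json(
    lapply(reports, function(r) r[c("rmse", "r_coef", "frac_le", "n", "scope")]),
    p, auto_unbox = TRUE, digits = NA))

  selected <- select_model(list(ann, svr), reports[c("ann", "svr")])
  sel_name <- c("ann", "svr")[attr(selected, "selected_index")]

  imp <- pipeline_stage("importance",
    feature_importance(selected, cohort, screen))
  wr("importance.csv", function(p)
    utils::write.csv(as.data.frame(imp), p, row.names = FALSE))

  manifest <- list(
    package = "ovaresp",
    version = as.character(utils::packageVersion("ovaresp")),
    seed = config$seed,
    n = nrow(cohort),
    alpha = config$alpha,
    n_selected_features = length(feats),
    selected_model = sel_name,
    rmse = list(ann = reports$ann$rmse, svr = reports$svr$rmse),
    r_coef = list(ann = reports$ann$r_coef, svr = reports$svr$r_coef),
    artifacts = lapply(paths, function(p)
      unname(tools::md5sum(p)))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  unlink(marker)
  invisible(manifest)
}

#' Iteratively tailor the Gn dose toward a target oocyte number
#'
#' Formalizes trial-and-error dose adjustment as bracketed bisection on the
#' gonadotropin-dosage axis: a 16-point pre-scan of the dose range locates an
#' interval whose predictions bracket the target (the direction of adjustment
#' follows the positive impact of dose on predicted yield), then bisection
#' refines the dose until the prediction is within `tolerance` oocytes of the
#' target. If no dose in the range reaches the target, the boundary dose with
#' the closest prediction is returned and flagged as not achievable.
#'
#' @param model a trained `ovr_model` whose inputs include `dosage_gn`.
#' @param baseline a one-row data frame with the patient's fixed non-dose
#'   features (any `dosage_gn` value present is ignored during the search).
#' @param target_count desired number of oocytes.
#' @param dose_bounds numeric `c(min, max)` admissible Gn dose.
#' @param tolerance acceptable |prediction - target| (oocytes), default 0.5.
#' @param max_iter maximum bisection iterations, default 50.
#' @return A list of class `ovr_tailoring`: `dose`, `prediction`, `achieved`
#'   (logical), `iterations`, and `trace` (data frame of every dose tried and
#'   its prediction).
#' @export
tailor_gn_dose <- function(model, baseline, target_count,
                           dose_bounds = c(300, 6000), tolerance = 0.5,
                           max_iter = 50) {
  if (!"dosage_gn" %in% model$features)
    stop("model inputs do not include dosage_gn")
  if (dose_bounds[1] >= dose_bounds[2]) stop("dose bounds must satisfy min < max")
  if (tolerance <= 0) stop("tolerance must be positive")
  baseline <- as.data.frame(baseline)
  if (nrow(baseline) != 1) stop("baseline must be a single record")

  trace <- data.frame(dose = numeric(0), prediction = numeric(0))
  pred_at <- function(dose) {
    rec <- baseline
    rec$dosage_gn <- dose
    p <- suppressWarnings(stats::predict(model, rec))
    if (!is.finite(p)) stop("model produced a non-finite prediction")
    trace <<- rbind(trace, data.frame(dose = dose, prediction = p))
    p
  }
  done <- function(dose, pred, achieved, iterations) {
    structure(list(dose = dose, prediction = pred, achieved = achieved,
                   iterations = iterations, trace = trace),
              class = "ovr_tailoring")
  }

  # fixed point: the baseline dose may already meet the target
  if ("dosage_gn" %in% names(baseline)) {
    d0 <- baseline$dosage_gn
    if (is.finite(d0) && d0 >= dose_bounds[1] && d0 <= dose_bounds[2]) {
      p0 <- pred_at(d0)
      if (abs(p0 - target_count) <= tolerance) return(done(d0, p0, TRUE, 1L))
    }
  }

  # pre-scan: 16-point grid to find a bracketing interval (handles models
  # that are not globally monotone in dose)
  grid <- seq(dose_bounds[1], dose_bounds[2], length.out = 16)
  preds <- vapply(grid, pred_at, numeric(1))
  resid <- preds - target_count
  hit <- which(abs(resid) <= tolerance)
  if (length(hit))
    return(done(grid[hit[1]], preds[hit[1]], TRUE, nrow(trace)))
  cross <- which(resid[-1] * resid[-length(resid)] < 0)
  if (!length(cross)) {
    # target unreachable in range: boundary dose with the closest prediction
    j <- which.min(abs(resid))
    return(done(grid[j], preds[j], FALSE, nrow(trace)))
  }
  lo <- grid[cross[1]]; hi <- grid[cross[1] + 1]
  f_lo <- resid[cross[1]]
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    mid <- (lo + hi) / 2
    p_mid <- pred_at(mid)
    if (abs(p_mid - target_count) <= tolerance)
      return(done(mid, p_mid, TRUE, nrow(trace)))
    if ((p_mid - target_count) * f_lo < 0) {
      hi <- mid
    } else {
      lo <- mid
      f_lo <- p_mid - target_count
    }
  }
  p_lo <- pred_at((lo + hi) / 2)
  done((lo + hi) / 2, p_lo, abs(p_lo - target_count) <= tolerance,
       nrow(trace))
}

#' @export
print.ovr_tailoring <- function(x, ...) {
  cat("Gn dose tailoring:", if (x$achieved) "target achieved" else
    "target NOT achievable within bounds", "\n")
  cat(sprintf("  recommended dose: %.1f IU -> predicted %.2f oocytes (%d evaluations)\n",
              x$dose, x$prediction, nrow(x$trace)))
  invisible(x)
}

#' Ovarian-response risk flag
#'
#' Classifies a predicted oocyte count: fewer than 6 oocytes signals a poor
#' response (risk of the IVF cycle being canceled), more than 18 a high
#' response (risk of ovarian hyperstimulation syndrome); anything in between
#' is a normal response. Thresholds are applied to the unrounded prediction
#' with strict inequalities.
#'
#' @param predicted_count numeric vector of predicted oocyte counts.
#' @return Character vector: `"poor"`, `"normal"` or `"high"`.
#' @examples
#' flag_response_risk(c(5.2, 11.18, 18, 18.01))
#' @export
flag_response_risk <- function(predicted_count) {
  if (any(!is.finite(predicted_count)))
    stop("predicted count must be finite")
  ifelse(predicted_count < 6, "poor",
         ifelse(predicted_count > 18, "high", "normal"))
}
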