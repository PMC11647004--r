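#' Define one pipeline configuration
#'
#' A pipeline spec fixes the Figure-of-merit choices explored by the study
#' workflow: spatial scale, dosimetric feature group, whether redundancy
#' screening of the dosiomics is applied, and the survival model.
#'
#' @param model `"cox"`, `"cox_lasso"`, `"cox_bootstrap_lasso"` or `"rsf"`.
#' @param feature_group `"mean_dose"`, `"dose_volume"`, `"firstorder"` or
#'   `"dosiomics_full"`.
#' @param scale `"whole_heart"` or `"subparts"`.
#' @param screening Apply clustering-based redundancy elimination; only
#'   meaningful (and only allowed) for the dosiomics groups.
#' @return A `pipeline_spec`.
#' @export
pipeline_spec <- function(model = c("cox", "cox_lasso",
                                    "cox_bootstrap_lasso", "rsf"),
                          feature_group = c("mean_dose", "dose_volume",
                                            "firstorder", "dosiomics_full"),
                          scale = c("whole_heart", "subparts"),
                          screening = FALSE) {
  model <- match.arg(model)
  feature_group <- match.arg(feature_group)
  scale <- match.arg(scale)
  if (screening && !feature_group %in% c("firstorder", "dosiomics_full"))
    stop("screening applies to the dosiomics feature groups only",
         call. = FALSE)
  structure(list(model = model, feature_group = feature_group,
                 scale = scale, screening = screening),
            class = "pipeline_spec")
}

spec_label <- function(spec) {
  paste(spec$model, spec$feature_group, spec$scale,
        if (spec$screening) "screened" else "all", sep = "|")
}

#' @export
print.pipeline_spec <- function(x, ...) {
  cat("<pipeline_spec>", spec_label(x), "\n")
  invisible(x)
}

#' The default 16-spec experiment grid
#'
#' Four baseline specs (Cox on the mean heart dose, Cox / Cox Lasso / RSF on
#' the dose-volume indicators) plus the three learned models crossed with
#' the two dosiomics groups and the two spatial scales (with redundancy
#' screening).
#'
#' @return List of 16 [pipeline_spec()] objects.
#' @export
default_pipeline_specs <- function() {
  specs <- list(
    pipeline_spec("cox", "mean_dose", "whole_heart"),
    pipeline_spec("cox", "dose_volume", "whole_heart"),
    pipeline_spec("cox_lasso", "dose_volume", "whole_heart"),
    pipeline_spec("rsf", "dose_volume", "whole_heart"))
  for (model in c("cox_lasso", "cox_bootstrap_lasso", "rsf"))
    for (group in c("firstorder", "dosiomics_full"))
      for (scale in c("whole_heart", "subparts"))
        specs[[length(specs) + 1L]] <-
          pipeline_spec(model, group, scale, screening = TRUE)
  specs
}

# Clinical covariates used for the censoring model: everything clinical
# except the first-diagnosis indicators.
ipcw_covariate_columns <- function() {
  c("sex", "age_6_10", "age_11_15", "age_gt15", "anthracyclines",
    "alkylating_agents")
}

spec_columns <- function(spec, feature_names) {
  clin <- setdiff(feature_names[!grepl("__", feature_names)], "patient_id")
  c(clin, feature_group_columns(feature_names, spec$feature_group,
                                spec$scale))
}

# Fit one spec on a training table: screening, optional tuning, model fit,
# censoring model. Everything is estimated from the training rows only.
fit_pipeline <- function(spec, train_features, train_outcomes,
                         screening_cfg = screening_config(),
                         hyperparams = list(), rsf_grid = NULL, seed = 1) {
  scr <- screen_predictors(train_features, train_outcomes,
                           config = screening_cfg,
                           cluster_dosiomics = spec$screening)
  train_kept <- apply_screening(scr, train_features)
  hp <- hyperparams
  if (spec$model == "rsf" && !is.null(rsf_grid) && nrow(rsf_grid) > 1) {
    tuned <- tune_hyperparameters("rsf", train_kept, train_outcomes,
                                  rsf_grid, seed = derive_seed(seed, "tune"))
    hp <- modifyList(hp, tuned$best)
  } else if (spec$model == "rsf" && !is.null(rsf_grid)) {
    hp <- modifyList(hp, as.list(rsf_grid[1, , drop = FALSE]))
  }
  model <- fit_model(spec$model, train_kept, train_outcomes,
                     hyperparams = hp, seed = derive_seed(seed, "fit"))
  cm <- fit_censoring_model(
    train_outcomes,
    train_features[intersect(ipcw_covariate_columns(),
                             names(train_features))],
    type = "cox")
  list(screening = scr, model = model, censor_model = cm,
       hyperparams = hp)
}

evaluate_pipeline <- function(fitted, test_features, test_outcomes,
                              time_grid = 1:60) {
  test_kept <- apply_screening(fitted$screening, test_features)
  risk <- risk_score(fitted$model, test_kept)
  covars <- test_features[intersect(ipcw_covariate_columns(),
                                    names(test_features))]
  surv <- predict_survival(fitted$model, test_kept, time_grid)
  grid_use <- time_grid[time_grid <= max(test_outcomes$time)]
  tibble::tibble(
    harrell_c = suppressWarnings(
      harrell_c(risk, test_outcomes$time, test_outcomes$event)),
    ipcw_c = suppressWarnings(
      ipcw_c(risk, test_outcomes$time, test_outcomes$event,
             fitted$censor_model, covariates = covars)),
    ibs = suppressWarnings(
      integrated_brier(surv[, seq_along(grid_use), drop = FALSE],
                       test_outcomes$time, test_outcomes$event,
                       fitted$censor_model, grid_use, covariates = covars)),
    n_features = length(fitted$screening$kept_columns))
}

#' Stratified k-fold cross-validation of one pipeline spec
#'
#' For each fold, screening, hyperparameter tuning, model fitting and
#' censoring-model estimation are performed on the training folds only;
#' Harrell's C, the IPCW C-index and the integrated Brier score over
#' `time_grid` are computed on the held-out fold.
#'
#' @param spec A [pipeline_spec()].
#' @param cohort List with `records` (incl. `time`, `event`) and `features`
#'   (full feature table), e.g. from [build_cohort_features()].
#' @param k Number of folds.
#' @param seed Integer seed (folds and all fit substreams derive from it).
#' @param rsf_grid Optional hyperparameter grid for RSF tuning.
#' @param hyperparams Fixed hyperparameters (e.g. bootstrap-Lasso `n_boot`).
#' @param time_grid Evaluation grid in years for the integrated Brier score.
#' @param columns Optional explicit predictor columns (overrides the spec's
#'   feature-group selection).
#' @return A `cv_result`: per-fold metrics, fold assignment, fitted-fold
#'   metadata.
#' @export
run_cv <- function(spec, cohort, k = 5, seed = 1, rsf_grid = NULL,
                   hyperparams = list(), time_grid = 1:60, columns = NULL) {
  records <- cohort$records
  features <- cohort$features
  outcomes <- tibble::tibble(time = records$time, event = records$event)
  cols <- columns %||% spec_columns(spec, names(features))
  folds <- stratified_kfold(outcomes, k = k,
                            seed = derive_seed(seed, "folds"))
  rows <- vector("list", k)
  selected <- vector("list", k)
  for (f in seq_len(k)) {
    tr <- folds != f
    res <- tryCatch({
      fitted <- fit_pipeline(spec, features[tr, cols, drop = FALSE],
                             outcomes[tr, , drop = FALSE],
                             hyperparams = hyperparams,
                             rsf_grid = rsf_grid,
                             seed = derive_seed(seed, "fold", f))
      ev <- evaluate_pipeline(fitted, features[!tr, cols, drop = FALSE],
                              outcomes[!tr, , drop = FALSE], time_grid)
      selected[[f]] <- if (inherits(fitted$model, "cox_fit"))
        fitted$model$selected_features else fitted$screening$kept_columns
      ev
    }, error = function(e) {
      warning("fold ", f, " failed: ", conditionMessage(e), call. = FALSE)
      NULL
    })
    rows[[f]] <- if (is.null(res)) tibble::tibble(
      harrell_c = NA_real_, ipcw_c = NA_real_, ibs = NA_real_,
      n_features = NA_integer_) else res
  }
  structure(list(spec = spec,
                 folds = dplyr::bind_cols(
                   tibble::tibble(fold = seq_len(k)),
                   dplyr::bind_rows(rows)),
                 fold_assignment = folds,
                 selected_features = selected,
                 seed = seed),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat("<cv_result>", spec_label(x$spec), "\n")
  print(glance(x))
  invisible(x)
}

#' @method tidy cv_result
#' @export
tidy.cv_result <- function(x, ...) {
  dplyr::bind_cols(tibble::tibble(spec = spec_label(x$spec)), x$folds)
}

#' @method glance cv_result
#' @export
glance.cv_result <- function(x, ...) {
  tibble::tibble(
    spec = spec_label(x$spec),
    model = x$spec$model,
    feature_group = x$spec$feature_group,
    scale = x$spec$scale,
    screening = x$spec$screening,
    harrell_c = mean(x$folds$harrell_c, na.rm = TRUE),
    harrell_c_sd = sd(x$folds$harrell_c, na.rm = TRUE),
    ipcw_c = mean(x$folds$ipcw_c, na.rm = TRUE),
    ipcw_c_sd = sd(x$folds$ipcw_c, na.rm = TRUE),
    ibs = mean(x$folds$ibs, na.rm = TRUE),
    ibs_sd = sd(x$folds$ibs, na.rm = TRUE))
}

#' Bootstrap out-of-bag time-dependent error curves
#'
#' Draws bootstrap samples of the cohort; on each, every spec's pipeline is
#' refitted on the in-bag rows (hyperparameters fixed) and the Brier score
#' BS(tau) and the bounded IPCW concordance C_tau are computed on the
#' out-of-bag rows at every grid time. Horizons with no usable pairs are
#' flagged missing and excluded from the mean curves.
#'
#' @param specs List of [pipeline_spec()] (optionally named).
#' @param cohort As in [run_cv()].
#' @param n_boot Number of bootstrap replicates.
#' @param time_grid Horizons in years.
#' @param seed Integer seed.
#' @param hyperparams Named list (by spec label) of fixed hyperparameters.
#' @return An `error_curves` object: tibble `curves` with one row per
#'   (spec, replicate, tau) and the per-tau `mean_curves`.
#' @export
bootstrap_error_curves <- function(specs, cohort, n_boot = 100,
                                   time_grid = 1:60, seed = 1,
                                   hyperparams = list()) {
  if (inherits(specs, "pipeline_spec")) specs <- list(specs)
  records <- cohort$records
  features <- cohort$features
  outcomes <- tibble::tibble(time = records$time, event = records$event)
  n <- nrow(records)
  out <- list()
  for (b in seq_len(n_boot)) {
    inbag <- with_seed(derive_seed(seed, "curve-boot", b), {
      repeat {
        i <- sample.int(n, n, replace = TRUE)
        if (sum(outcomes$event[i]) >= 2 &&
            sum(outcomes$event[-unique(i)]) >= 1) break
      }
      i
    })
    oob <- setdiff(seq_len(n), unique(inbag))
    for (s in seq_along(specs)) {
      spec <- specs[[s]]
      lab <- names(specs)[s] %||% spec_label(spec)
      if (lab == "") lab <- spec_label(spec)
      cols <- spec_columns(spec, names(features))
      curves <- tryCatch({
        fitted <- fit_pipeline(
          spec, features[inbag, cols, drop = FALSE],
          outcomes[inbag, , drop = FALSE],
          hyperparams = hyperparams[[lab]] %||% list(),
          seed = derive_seed(seed, "curve-fit", b, s))
        test_f <- features[oob, cols, drop = FALSE]
        test_o <- outcomes[oob, , drop = FALSE]
        test_kept <- apply_screening(fitted$screening, test_f)
        covars <- features[oob, intersect(ipcw_covariate_columns(),
                                          names(features)), drop = FALSE]
        risk <- risk_score(fitted$model, test_kept)
        surv <- predict_survival(fitted$model, test_kept, time_grid)
        grid_use <- time_grid <= max(test_o$time)
        bc <- rep(NA_real_, length(time_grid))
        bc[grid_use] <- suppressWarnings(
          brier_curve(surv[, grid_use, drop = FALSE], test_o$time,
                      test_o$event, fitted$censor_model,
                      time_grid[grid_use], covariates = covars)$brier)
        ct <- suppressWarnings(
          ipcw_c_curve(risk, test_o$time, test_o$event,
                       fitted$censor_model, covariates = covars,
                       taus = time_grid)$c_index)
        tibble::tibble(spec = lab, replicate = b, tau = time_grid,
                       brier = bc, c_tau = ct)
      }, error = function(e) {
        warning("replicate ", b, " (", lab, ") failed: ",
                conditionMessage(e), call. = FALSE)
        tibble::tibble(spec = lab, replicate = b, tau = time_grid,
                       brier = NA_real_, c_tau = NA_real_)
      })
      out[[length(out) + 1L]] <- curves
    }
  }
  curves <- dplyr::bind_rows(out)
  mean_curves <- curves |>
    dplyr::group_by(.data$spec, .data$tau) |>
    dplyr::summarise(
      brier = mean(.data$brier, na.rm = TRUE),
      c_tau = mean(.data$c_tau, na.rm = TRUE),
      n_used = sum(!is.na(.data$c_tau)), .groups = "drop")
  structure(list(curves = curves, mean_curves = mean_curves,
                 time_grid = time_grid, n_boot = n_boot, seed = seed),
            class = "error_curves")
}

#' @export
print.error_curves <- function(x, ...) {
  cat(sprintf("<error_curves> %d replicate(s), %d spec(s), %d horizon(s)\n",
              x$n_boot, length(unique(x$curves$spec)),
              length(x$time_grid)))
  invisible(x)
}

#' @method tidy error_curves
#' @export
tidy.error_curves <- function(x, ...) {
  tidyr::pivot_longer(x$mean_curves, c("brier", "c_tau"),
                      names_to = "metric", values_to = "value")
}
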