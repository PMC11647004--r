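#' Default experiment profiles
#'
#' `"desk"` is sized for a single workstation run (2 000 patients, 20
#' bootstrap replicates for both the stability selection and the error
#' curves, a single coarse random-forest configuration); `"cohort"` matches
#' a full cohort-scale setup (7 367 patients, 100 bootstraps, a tuned
#' forest grid) and is correspondingly compute-hungry.
#'
#' @param profile `"desk"` or `"cohort"`.
#' @return Named list of profile settings.
#' @export
experiment_profile <- function(profile = c("desk", "cohort")) {
  profile <- match.arg(profile)
  if (profile == "desk")
    list(n_patients = 2000, n_boot = 20, cv_folds = 5,
         rsf_grid = data.frame(num_trees = 100, min_node_size = 15,
                               splitrule = "extratrees",
                               num_random_splits = 5,
                               stringsAsFactors = FALSE),
         run_curves = TRUE)
  else
    list(n_patients = 7367, n_boot = 100, cv_folds = 5,
         rsf_grid = expand.grid(num_trees = 500,
                                mtry_rule = c("sqrt", "third"),
                                min_node_size = c(5, 15, 50),
                                stringsAsFactors = FALSE),
         run_curves = TRUE)
}

resolve_rsf_grid <- function(grid, p) {
  if (is.null(grid)) return(NULL)
  if ("mtry_rule" %in% names(grid)) {
    grid$mtry <- ifelse(grid$mtry_rule == "third",
                        pmax(1L, floor(p / 3)),
                        pmax(1L, floor(sqrt(p))))
    grid$mtry_rule <- NULL
  }
  unique(grid)
}

#' Run the full synthetic-cohort experiment
#'
#' Executes the whole workflow for every requested pipeline spec: cohort
#' generation and feature extraction, stratified cross-validation of each
#' spec, a summary table (mean +- SD of Harrell's C, IPCW C and IBS, with
#' the per-column best flagged), a Wilcoxon comparison of the
#' best-per-model-class specs against the Cox mean-heart-dose reference, and
#' (optionally) bootstrap out-of-bag error curves for the representative
#' specs. Fully reproducible from the master seed.
#'
#' @param config Either a YAML file path or a list. Recognised entries:
#'   `seed` (master seed), `profile` (`"desk"`/`"cohort"`), `n_patients`,
#'   `n_boot`, `cv_folds`, `run_curves`, `specs` (list of lists with
#'   `model`, `feature_group`, `scale`, `screening`), and any
#'   [cohort_config()] argument under `cohort`.
#' @param out Optional output directory for CSV/JSON artifacts.
#' @return A `dosurv_experiment` bundle: `summary`, `folds`, `wilcoxon`,
#'   `curves`, `cohort_config`, `seed`.
#' @export
run_experiment <- function(config = list(), out = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  profile <- experiment_profile(config$profile %||% "desk")
  seed <- as.integer(config$seed %||% 1L)
  n_patients <- config$n_patients %||% profile$n_patients
  n_boot <- config$n_boot %||% profile$n_boot
  cv_folds <- config$cv_folds %||% profile$cv_folds
  run_curves <- config$run_curves %||% profile$run_curves

  cohort_args <- config$cohort %||% list()
  cohort_args$n_patients <- n_patients
  cohort_args$seed <- derive_seed(seed, "cohort")
  ccfg <- do.call(cohort_config, cohort_args)
  message("Generating cohort of ", n_patients, " patients ...")
  cohort <- build_cohort_features(ccfg)

  specs <- if (is.null(config$specs)) default_pipeline_specs() else
    lapply(config$specs, function(s) do.call(pipeline_spec, s))
  hyperparams <- list(n_boot = n_boot)

  cvs <- list()
  for (s in seq_along(specs)) {
    lab <- spec_label(specs[[s]])
    message("Cross-validating ", lab, " ...")
    p <- length(feature_group_columns(names(cohort$features),
                                      specs[[s]]$feature_group,
                                      specs[[s]]$scale))
    cvs[[lab]] <- run_cv(specs[[s]], cohort, k = cv_folds,
                         seed = derive_seed(seed, "cv", s),
                         rsf_grid = resolve_rsf_grid(profile$rsf_grid, p),
                         hyperparams = hyperparams)
  }

  summary <- dplyr::bind_rows(lapply(cvs, glance)) |>
    dplyr::mutate(
      best_harrell = .data$harrell_c == max(.data$harrell_c, na.rm = TRUE),
      best_ipcw = .data$ipcw_c == max(.data$ipcw_c, na.rm = TRUE),
      best_ibs = .data$ibs == min(.data$ibs, na.rm = TRUE))
  folds <- dplyr::bind_rows(lapply(cvs, tidy))

  wilcoxon <- experiment_wilcoxon(cvs, summary)

  curves <- NULL
  if (isTRUE(run_curves)) {
    reps <- representative_specs(cvs, summary)
    message("Bootstrap error curves for ", length(reps), " spec(s) ...")
    curves <- bootstrap_error_curves(
      reps, cohort, n_boot = n_boot, seed = derive_seed(seed, "curves"),
      hyperparams = stats::setNames(
        rep(list(hyperparams), length(reps)), names(reps)))
  }

  bundle <- structure(
    list(summary = summary, folds = folds, wilcoxon = wilcoxon,
         curves = curves, cohort_config = ccfg, seed = seed,
         selected_features = lapply(cvs, `[[`, "selected_features")),
    class = "dosurv_experiment")
  if (!is.null(out)) write_experiment(bundle, out)
  bundle
}

# Reference model plus the best spec of each learned model class by mean
# IPCW C-index.
representative_specs <- function(cvs, summary) {
  reps <- list()
  for (lab in c("cox|mean_dose|whole_heart|all",
                "cox|dose_volume|whole_heart|all"))
    if (lab %in% names(cvs)) reps[[lab]] <- cvs[[lab]]$spec
  for (cls in c("cox_lasso", "cox_bootstrap_lasso", "rsf")) {
    rows <- summary[summary$model == cls, ]
    if (!nrow(rows)) next
    lab <- rows$spec[which.max(rows$ipcw_c)]
    reps[[lab]] <- cvs[[lab]]$spec
  }
  reps
}

experiment_wilcoxon <- function(cvs, summary) {
  ref_lab <- "cox|mean_dose|whole_heart|all"
  if (!ref_lab %in% names(cvs)) return(NULL)
  ref <- cvs[[ref_lab]]$folds$ipcw_c
  rows <- list()
  for (cls in c("cox_lasso", "cox_bootstrap_lasso", "rsf")) {
    sub <- summary[summary$model == cls, ]
    if (!nrow(sub)) next
    lab <- sub$spec[which.max(sub$ipcw_c)]
    p <- suppressWarnings(
      wilcoxon_compare(cvs[[lab]]$folds$ipcw_c[
        !is.na(cvs[[lab]]$folds$ipcw_c)], ref[!is.na(ref)]))
    rows[[cls]] <- tibble::tibble(reference = ref_lab, model_class = cls,
                                  best_spec = lab, p_value = p)
  }
  dplyr::bind_rows(rows)
}

#' Write an experiment bundle to disk
#'
#' Emits `summary.csv`, `folds.csv`, `wilcoxon.csv`, `curves.csv` (tidy:
#' spec, replicate, tau, metric, value) and `log.json` (seed, cohort
#' configuration, per-spec selected features).
#'
#' @param bundle A `dosurv_experiment`.
#' @param out Output directory.
#' @return `out`, invisibly.
#' @export
write_experiment <- function(bundle, out) {
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(bundle$summary, file.path(out, "summary.csv"),
                   row.names = FALSE)
  utils::write.csv(bundle$folds, file.path(out, "folds.csv"),
                   row.names = FALSE)
  if (!is.null(bundle$wilcoxon))
    utils::write.csv(bundle$wilcoxon, file.path(out, "wilcoxon.csv"),
                     row.names = FALSE)
  if (!is.null(bundle$curves)) {
    tidy_curves <- tidyr::pivot_longer(bundle$curves$curves,
                                       c("brier", "c_tau"),
                                       names_to = "metric",
                                       values_to = "value")
    utils::write.csv(tidy_curves, file.path(out, "curves.csv"),
                     row.names = FALSE)
  }
  cfg <- unclass(bundle$cohort_config)
  cfg$hazard_coefficients <- as.list(cfg$hazard_coefficients)
  jsonlite::write_json(
    list(seed = bundle$seed, cohort_config = cfg,
         selected_features = bundle$selected_features),
    file.path(out, "log.json"), auto_unbox = TRUE, digits = NA)
  invisible(out)
}

#' @export
print.dosurv_experiment <- function(x, ...) {
  cat("<dosurv_experiment> seed", x$seed, "\n")
  print(dplyr::select(x$summary, "spec", "harrell_c", "ipcw_c", "ibs",
                      dplyr::starts_with("best_")), n = Inf)
  invisible(x)
}

#' @method tidy dosurv_experiment
#' @export
tidy.dosurv_experiment <- function(x, ...) {
  x$summary
}

#' Plot cross-validated metrics of an experiment
#'
#' One panel per metric; points are fold means with +-1 SD bars, mirroring
#' the usual presentation of stratified-cross-validation results.
#'
#' @param object A `dosurv_experiment`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot dosurv_experiment
#' @export
autoplot.dosurv_experiment <- function(object, ...) {
  long <- object$summary |>
    tidyr::pivot_longer(c("harrell_c", "ipcw_c", "ibs"),
                        names_to = "metric", values_to = "mean") |>
    dplyr::mutate(sd = dplyr::case_when(
      .data$metric == "harrell_c" ~ .data$harrell_c_sd,
      .data$metric == "ipcw_c" ~ .data$ipcw_c_sd,
      TRUE ~ .data$ibs_sd))
  ggplot2::ggplot(long,
                  ggplot2::aes(x = .data$spec, y = .data$mean,
                               colour = .data$model)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$mean - .data$sd,
                                          ymax = .data$mean + .data$sd)) +
    ggplot2::facet_wrap(~metric, scales = "free_y", ncol = 1) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_bw()
}

#' Plot bootstrap out-of-bag error curves
#'
#' Mean Brier score and bounded IPCW concordance across horizons, one line
#' per spec.
#'
#' @param object An `error_curves` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot error_curves
#' @export
autoplot.error_curves <- function(object, ...) {
  long <- tidy(object)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$tau, y = .data$value,
                                     colour = .data$spec)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "time (years)", y = NULL) +
    ggplot2::theme_bw()
}

#' Plot per-fold metric distributions of one cross-validated spec
#'
#' @param object A `cv_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot cv_result
#' @export
autoplot.cv_result <- function(object, ...) {
  long <- tidyr::pivot_longer(object$folds, c("harrell_c", "ipcw_c", "ibs"),
                              names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$metric, y = .data$value)) +
    ggplot2::geom_boxplot() +
    ggplot2::geom_point() +
    ggplot2::labs(title = spec_label(object$spec), x = NULL, y = NULL) +
    ggplot2::theme_bw()
}
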