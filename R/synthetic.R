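#' Configuration for the synthetic cohort generator
#'
#' Defines the study conditions the generator emulates: a large cohort with
#' roughly 95% right censoring and 5% events over a 60-year horizon, a
#' non-irradiated subgroup, heart grids of up to `max_region_shape` voxels at
#' 2 mm spacing, multi-session courses, and a proportional-hazards event
#' process driven by dose summaries and chemotherapy on a Weibull baseline.
#'
#' @param n_patients Number of patients.
#' @param seed Integer seed; fully determines the cohort.
#' @param event_rate_target,censor_rate_target Target event and censoring
#'   fractions (must sum to ~1). The Weibull baseline scale is calibrated at
#'   construction so the realized event fraction matches the target.
#' @param voxel_spacing Voxel spacing in mm (default 2).
#' @param max_region_shape Upper bound of the heart grid in voxels.
#' @param n_diagnosis_groups Number of first-cancer diagnosis groups.
#' @param hazard_coefficients Named log-hazard coefficients; names resolve to
#'   covariate or dose-summary columns (e.g. `mean_heart_dose`, per Gy).
#' @param baseline_shape,baseline_scale Weibull baseline parameters (years);
#'   `baseline_scale = NULL` calibrates it to `event_rate_target`.
#' @param admin_censor_time Administrative censoring horizon in years.
#' @param zero_dose_fraction Fraction of patients with non-irradiated hearts.
#' @param censor_range Support of the uniform censoring-time distribution in
#'   years (independent censoring).
#' @param censor_coefficients Optional named coefficients making censoring
#'   depend on covariates (log scale applied to censoring times), used to
#'   exercise inverse-probability-of-censoring weighting.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_patients = 1000, seed = 1,
                          event_rate_target = 0.05,
                          censor_rate_target = 0.95,
                          voxel_spacing = 2,
                          max_region_shape = c(67, 70, 71),
                          n_diagnosis_groups = 42,
                          hazard_coefficients = c(mean_heart_dose = 0.08,
                                                  anthracyclines = 0.8,
                                                  alkylating_agents = 0.4,
                                                  dx_03 = 1.0,
                                                  dx_07 = 0.6),
                          baseline_shape = 2.8,
                          baseline_scale = NULL,
                          admin_censor_time = 60,
                          zero_dose_fraction = 0.45,
                          censor_range = c(2, 60),
                          censor_coefficients = NULL) {
  if (abs(event_rate_target + censor_rate_target - 1) > 0.01)
    stop("event and censor rate targets must sum to ~1", call. = FALSE)
  if (length(max_region_shape) != 3L || any(max_region_shape < 12))
    stop("`max_region_shape` must be a voxel triple of at least 12",
         call. = FALSE)
  if (voxel_spacing <= 0 || baseline_shape <= 0)
    stop("shapes and spacing must be positive", call. = FALSE)
  cfg <- structure(list(
    n_patients = as.integer(n_patients), seed = as.integer(seed),
    event_rate_target = event_rate_target,
    censor_rate_target = censor_rate_target,
    voxel_spacing = voxel_spacing,
    max_region_shape = as.integer(max_region_shape),
    min_region_shape = pmin(c(16L, 20L, 22L), as.integer(max_region_shape)),
    n_diagnosis_groups = as.integer(n_diagnosis_groups),
    hazard_coefficients = hazard_coefficients,
    baseline_shape = baseline_shape,
    baseline_scale = baseline_scale,
    admin_censor_time = admin_censor_time,
    zero_dose_fraction = zero_dose_fraction,
    censor_range = censor_range,
    censor_coefficients = censor_coefficients), class = "cohort_config")
  if (is.null(cfg$baseline_scale))
    cfg$baseline_scale <- calibrate_baseline_scale(cfg)
  cfg
}

#' @export
print.cohort_config <- function(x, ...) {
  cat(sprintf(paste0("<cohort_config> n=%d, seed=%d, target event rate ",
                     "%.1f%%, Weibull(%.2g, %.4g)\n"),
              x$n_patients, x$seed, 100 * x$event_rate_target,
              x$baseline_shape, x$baseline_scale))
  invisible(x)
}

# Draw the cheap marginals (covariates + realized mean heart dose) without
# building volumes; the realized aggregated mean dose equals the sampled
# target by construction, so calibration against these marginals is exact
# up to Monte-Carlo error.
draw_patient_marginals <- function(cfg, n) {
  ndx <- cfg$n_diagnosis_groups
  dxw <- 1 / (seq_len(ndx) + 2)
  tibble::tibble(
    sex = rbinom(n, 1, 0.449),
    age_category = factor(
      sample(c("0-5", "6-10", "11-15", ">15"), n, replace = TRUE,
             prob = c(0.539, 0.202, 0.213, 0.046)),
      levels = c("0-5", "6-10", "11-15", ">15")),
    dx_group = sample.int(ndx, n, replace = TRUE, prob = dxw / sum(dxw)),
    anthracyclines = rbinom(n, 1, 0.35),
    alkylating_agents = rbinom(n, 1, 0.55),
    irradiated = as.integer(runif(n) >= cfg$zero_dose_fraction),
    mean_heart_dose = .data$irradiated *
      pmin(pmax(exp(rnorm(n, log(1.8), 1.2)), 0.02), 48))
}

dx_indicator_matrix <- function(dx_group, ndx) {
  m <- matrix(0, length(dx_group), ndx)
  m[cbind(seq_along(dx_group), dx_group)] <- 1
  colnames(m) <- sprintf("dx_%02d", seq_len(ndx))
  tibble::as_tibble(m)
}

linear_predictor <- function(coefs, data) {
  lp <- rep(0, nrow(data))
  for (nm in names(coefs)) {
    if (!nm %in% names(data))
      stop("hazard coefficient '", nm, "' matches no covariate or dose ",
           "summary", call. = FALSE)
    lp <- lp + coefs[[nm]] * as.numeric(data[[nm]])
  }
  if (any(!is.finite(lp)))
    stop("non-finite linear predictor", call. = FALSE)
  lp
}

calibrate_baseline_scale <- function(cfg, n = 20000) {
  with_seed(derive_seed(cfg$seed, "calibration"), {
    cov <- draw_patient_marginals(cfg, n)
    cov <- dplyr::bind_cols(cov, dx_indicator_matrix(cov$dx_group,
                                                     cfg$n_diagnosis_groups))
    lp <- linear_predictor(cfg$hazard_coefficients, cov)
    u <- runif(n)
    cens <- pmin(runif(n, cfg$censor_range[1], cfg$censor_range[2]),
                 cfg$admin_censor_time)
    k <- cfg$baseline_shape
    event_rate <- function(s) {
      t_ev <- s * (-log(u) / exp(lp))^(1 / k)
      mean(t_ev <= cens)
    }
    stats::uniroot(function(s) event_rate(s) - cfg$event_rate_target,
                   lower = 1, upper = 1e5, tol = 1e-3)$root
  })
}

#' Simulate right-censored survival outcomes under a Weibull-baseline
#' proportional-hazards model
#'
#' Event times follow a proportional-hazards model with Weibull baseline
#' cumulative hazard \eqn{\Lambda_0(t) = (t/scale)^{shape}} and linear
#' predictor `config$hazard_coefficients` applied to the covariate and
#' dose-summary columns. Censoring times are drawn independently (uniform on
#' `config$censor_range`, administratively capped) unless
#' `config$censor_coefficients` makes them covariate-dependent.
#'
#' @param covariates Tibble of covariate columns (one row per patient).
#' @param dose_summaries Tibble of dose summaries (e.g. `mean_heart_dose`),
#'   or NULL if those columns are already in `covariates`.
#' @param config A [cohort_config()].
#' @param seed Optional seed override (defaults to a substream of
#'   `config$seed`).
#' @return Tibble with columns `time` (years) and `event` (0/1).
#' @export
simulate_survival <- function(covariates, dose_summaries = NULL, config,
                              seed = NULL) {
  data <- if (is.null(dose_summaries)) covariates else
    dplyr::bind_cols(covariates, dose_summaries)
  lp <- linear_predictor(config$hazard_coefficients, data)
  n <- nrow(data)
  with_seed(seed %||% derive_seed(config$seed, "survival"), {
    u <- runif(n)
    t_event <- config$baseline_scale *
      (-log(u) / exp(lp))^(1 / config$baseline_shape)
    cens <- runif(n, config$censor_range[1], config$censor_range[2])
    if (!is.null(config$censor_coefficients))
      cens <- cens * exp(-linear_predictor(config$censor_coefficients, data))
    cens <- pmin(cens, config$admin_censor_time)
    tibble::tibble(time = pmin(t_event, cens),
                   event = as.integer(t_event <= cens))
  })
}

# Ellipsoidal whole-heart mask with five disjoint subparts: an outer
# myocardial shell and four chambers obtained by cutting the inner ellipsoid
# at the centre along x (left/right) and z (atria above, ventricles below).
make_heart_masks <- function(dims) {
  cx <- (dims + 1) / 2
  ax <- dims * 0.45
  x2 <- ((seq_len(dims[1]) - cx[1]) / ax[1])^2
  y2 <- ((seq_len(dims[2]) - cx[2]) / ax[2])^2
  z2 <- ((seq_len(dims[3]) - cx[3]) / ax[3])^2
  r2 <- outer(outer(x2, y2, "+"), z2, "+")
  whole <- r2 <= 1
  inner <- r2 <= 0.72^2
  left <- array(rep(seq_len(dims[1]) >= cx[1], prod(dims[2:3])), dims)
  top <- array(rep(seq_len(dims[3]) >= cx[3], each = prod(dims[1:2])), dims)
  list(whole_heart = whole,
       left_atrium = inner & left & top,
       right_atrium = inner & !left & top,
       left_ventricle = inner & left & !top,
       right_ventricle = inner & !left & !top,
       myocardium = whole & !inner)
}

# Axis-aligned Gaussian "beam" fields plus noise give the local dose
# heterogeneity of real plans without modelling beam geometry.
random_dose_field <- function(dims) {
  nb <- sample(1:3, 1, prob = c(0.5, 0.35, 0.15))
  field <- array(0, dims)
  for (b in seq_len(nb)) {
    centre <- runif(3, 0.25, 0.75) * dims
    sigma <- runif(3, 0.15, 0.35) * dims
    amp <- runif(1, 0.5, 1.5)
    gx <- exp(-0.5 * ((seq_len(dims[1]) - centre[1]) / sigma[1])^2)
    gy <- exp(-0.5 * ((seq_len(dims[2]) - centre[2]) / sigma[2])^2)
    gz <- exp(-0.5 * ((seq_len(dims[3]) - centre[3]) / sigma[3])^2)
    field <- field + amp * outer(gx, outer(gy, gz))
  }
  noise <- array(rnorm(prod(dims), 0, 0.05 * max(field)), dims)
  pmax(field + noise, 0)
}

#' Generate one patient's radiotherapy course
#'
#' Draws 1-3 sessions on a common per-patient heart grid (each dimension
#' between `config$min_region_shape` and `config$max_region_shape`), with
#' spatially smooth random dose fields scaled so the six-month
#' window-aggregated whole-heart mean dose equals the patient's sampled
#' target (0 for the non-irradiated subgroup, otherwise log-normal, capped
#' at 48 Gy).
#'
#' @param config A [cohort_config()].
#' @param patient_id Integer patient index (determines the substream).
#' @return An [rt_course()].
#' @export
generate_dose_course <- function(config, patient_id) {
  with_seed(derive_seed(config$seed, "course", patient_id), {
    lo <- config$min_region_shape
    hi <- config$max_region_shape
    dims <- as.integer(round(lo + stats::rbeta(3, 2, 3) * (hi - lo)))
    masks <- make_heart_masks(dims)
    irradiated <- runif(1) >= config$zero_dose_fraction
    target <- if (irradiated)
      min(max(exp(rnorm(1, log(1.8), 1.2)), 0.02), 48) else 0
    n_sessions <- sample(1:3, 1, prob = c(0.65, 0.25, 0.10))
    offsets <- cumsum(c(0, round(runif(n_sessions - 1, 7, 200))))
    fields <- lapply(seq_len(n_sessions), function(s) {
      if (irradiated) random_dose_field(dims) else array(0, dims)
    })
    if (irradiated) {
      in_window <- offsets <= 183
      agg <- Reduce(`+`, fields[in_window])
      cur <- mean(agg[masks$whole_heart])
      scale <- if (cur > 1e-12) target / cur else 0
      fields <- lapply(fields, function(f) f * scale)
    }
    sessions <- lapply(fields, function(f)
      new_dose_volume(f, spacing = rep(config$voxel_spacing, 3L),
                      masks = masks))
    rt_course(sessions, offsets)
  })
}

# Covariates for one batch of patients, on the cohort's covariate substream.
draw_cohort_covariates <- function(config) {
  with_seed(derive_seed(config$seed, "covariates"), {
    cov <- draw_patient_marginals(config, config$n_patients)
    dplyr::bind_cols(
      tibble::tibble(patient_id = sprintf("P%05d",
                                          seq_len(config$n_patients))),
      dplyr::select(cov, -"mean_heart_dose", -"irradiated"),
      dx_indicator_matrix(cov$dx_group, config$n_diagnosis_groups)) |>
      dplyr::select(-"dx_group")
  })
}

#' Generate a synthetic cohort
#'
#' Draws covariates, one radiotherapy course per patient, and right-censored
#' survival outcomes whose hazard depends on the realized dose summaries and
#' chemotherapy. Identical seeds give identical cohorts.
#'
#' @param config A [cohort_config()].
#' @param keep_courses Keep the generated [rt_course()] objects (default).
#'   Set to FALSE for large cohorts where only the patient table (including
#'   the realized `mean_heart_dose`) is needed.
#' @param volumes Generate the 3D dose fields (default). With
#'   `volumes = FALSE` the whole-heart mean dose is drawn directly from the
#'   same marginal the dose fields are scaled to, giving a statistically
#'   identical patient table at a fraction of the cost (per-patient values
#'   differ from a `volumes = TRUE` run because the draws consume different
#'   substreams).
#' @return List with `records` (tibble: identifiers, covariates,
#'   `mean_heart_dose`, `time`, `event`) and `courses` (named list of
#'   [rt_course()], or NULL).
#' @export
generate_cohort <- function(config, keep_courses = TRUE, volumes = TRUE) {
  if (config$n_patients < 2)
    stop("`n_patients` must be at least 2", call. = FALSE)
  records <- draw_cohort_covariates(config)
  courses <- NULL
  if (volumes) {
    courses <- if (keep_courses) vector("list", config$n_patients) else NULL
    mhd <- numeric(config$n_patients)
    for (i in seq_len(config$n_patients)) {
      course <- generate_dose_course(config, i)
      agg <- aggregate_sessions(course)
      mhd[i] <- mean_dose(agg, "whole_heart")
      if (keep_courses) courses[[i]] <- course
    }
    if (keep_courses) names(courses) <- records$patient_id
  } else {
    mhd <- with_seed(derive_seed(config$seed, "meandose"), {
      irr <- runif(config$n_patients) >= config$zero_dose_fraction
      irr * pmin(pmax(exp(rnorm(config$n_patients, log(1.8), 1.2)),
                      0.02), 48)
    })
  }
  records$mean_heart_dose <- mhd
  outcome <- simulate_survival(records, NULL, config)
  records <- dplyr::bind_cols(records, outcome)
  list(records = records, courses = courses)
}

#' Generate a cohort and its full feature table in one streamed pass
#'
#' Equivalent to [generate_cohort()] followed by [extract_feature_table()]
#' with `group = "all"` over both scales, but each course is preprocessed,
#' measured and discarded immediately, so cohorts of thousands of patients
#' fit in memory.
#'
#' @inheritParams generate_cohort
#' @param window_days,clip_quantile,bin_width Preprocessing parameters.
#' @return List with `records` and `features` (tibble: `patient_id`,
#'   clinical columns, all dosimetric columns over the whole heart and the
#'   five subparts).
#' @export
build_cohort_features <- function(config, window_days = 183,
                                  clip_quantile = 0.98, bin_width = 0.5) {
  if (config$n_patients < 2)
    stop("`n_patients` must be at least 2", call. = FALSE)
  records <- draw_cohort_covariates(config)
  regions <- heart_regions()
  mhd <- numeric(config$n_patients)
  feats <- vector("list", config$n_patients)
  for (i in seq_len(config$n_patients)) {
    course <- generate_dose_course(config, i)
    agg <- aggregate_sessions(course, window_days)
    mhd[i] <- mean_dose(agg, "whole_heart")
    vol <- clip_outliers(agg, quantile = clip_quantile)
    feats[[i]] <- unlist(lapply(regions, function(r)
      extract_region_features(vol, r, "all", bin_width)))
  }
  records$mean_heart_dose <- mhd
  outcome <- simulate_survival(records, NULL, config)
  records <- dplyr::bind_cols(records, outcome)
  features <- dplyr::bind_cols(clinical_columns(records),
                               tibble::as_tibble(do.call(rbind, feats)))
  list(records = records, features = features)
}

#' Write a cohort to disk
#'
#' The patient table goes to `cohort.csv`, the configuration to
#' `config.yaml`, and (when courses are present) each session's dose and
#' masks to per-patient NIfTI files.
#'
#' @param cohort Result of [generate_cohort()].
#' @param config The [cohort_config()] used.
#' @param path Output directory.
#' @param write_volumes Write per-session NIfTI volumes (default FALSE).
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, config, path, write_volumes = FALSE) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(cohort$records, file.path(path, "cohort.csv"),
                   row.names = FALSE)
  cfg <- config
  cfg$hazard_coefficients <- as.list(cfg$hazard_coefficients)
  yaml::write_yaml(unclass(cfg), file.path(path, "config.yaml"))
  if (write_volumes && !is.null(cohort$courses)) {
    for (pid in names(cohort$courses)) {
      course <- cohort$courses[[pid]]
      for (s in seq_along(course$sessions))
        write_dose_volume(course$sessions[[s]], file.path(path, pid),
                          prefix = sprintf("session%02d", s))
    }
  }
  invisible(path)
}
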