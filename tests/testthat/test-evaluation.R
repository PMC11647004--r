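test_that("Harrell's C handles the worked 5-subject example and edge cases", {
  times <- c(2, 4, 6, 8, 10)
  events <- c(1, 1, 0, 1, 0)
  # hand enumeration with risks (1,5,4,2,3): comparable pairs are
  # subject 1 vs {2,3,4,5} (0 concordant), 2 vs {3,4,5} (3), 4 vs {5} (0)
  expect_equal(harrell_c(c(1, 5, 4, 2, 3), times, events), 3 / 8)
  # perfectly anti-ordered risks with no censoring
  expect_equal(harrell_c(5:1, 1:5, rep(1, 5)), 1)
  # all-tied risks
  expect_equal(harrell_c(rep(2, 5), times, events), 0.5)
  expect_warning(out <- harrell_c(1:3, c(5, 4, 3), c(0, 0, 0)),
                 "no comparable")
  expect_true(is.na(out))
})

test_that("Harrell's C matches brute force and survival::concordance", {
  withr::with_seed(19, {
    for (r in 1:20) {
      d <- random_censored_data(n = 60)
      got <- harrell_c(d$risk, d$time, d$event)
      expect_equal(got, oracle_harrell(d$risk, d$time, d$event),
                   tolerance = 1e-12)
      ref <- survival::concordance(survival::Surv(d$time, d$event) ~ d$risk,
                                   reverse = TRUE)$concordance
      expect_equal(got, ref, tolerance = 1e-9)
    }
  })
})

test_that("IPCW concordance equals Harrell's C without censoring", {
  withr::with_seed(23, {
    for (r in 1:5) {
      d <- random_censored_data(n = 50, cens_frac = 0)
      cm <- fit_censoring_model(tibble::tibble(time = d$time,
                                               event = d$event))
      expect_identical(ipcw_c(d$risk, d$time, d$event, cm),
                       harrell_c(d$risk, d$time, d$event))
    }
  })
})

test_that("IPCW concordance matches the hand-weighted oracle", {
  withr::with_seed(29, {
    for (r in 1:20) {
      d <- random_censored_data(n = 50, cens_frac = 0.4)
      cm <- fit_censoring_model(tibble::tibble(time = d$time,
                                               event = d$event))
      expect_equal(ipcw_c(d$risk, d$time, d$event, cm),
                   oracle_ipcw_c(d$risk, d$time, d$event),
                   tolerance = 1e-6)
      # truncation beyond the last event equals the untruncated value
      expect_equal(ipcw_c(d$risk, d$time, d$event, cm,
                          truncation = max(d$time) + 1),
                   ipcw_c(d$risk, d$time, d$event, cm), tolerance = 1e-12)
      # bounded C_tau with an interior horizon matches the oracle too
      tau <- median(d$time)
      expect_equal(ipcw_c(d$risk, d$time, d$event, cm, truncation = tau),
                   oracle_ipcw_c(d$risk, d$time, d$event, tau),
                   tolerance = 1e-6)
    }
  })
})

test_that("an 8-subject IPCW example matches fully hand-computed weights", {
  time <- c(1, 2, 3, 4, 5, 6, 7, 8)
  event <- c(1, 0, 1, 0, 1, 0, 1, 0)
  risk <- c(8, 7, 6, 5, 4, 3, 2, 1)
  cm <- fit_censoring_model(tibble::tibble(time = time, event = event))
  # censoring KM drops at t = 2, 4, 6 with at-risk 7, 5, 3; the left limits
  # G(t-) at the event times 1, 3, 5, 7 are:
  g <- c(1, 6 / 7, 6 / 7 * 4 / 5, 6 / 7 * 4 / 5 * 2 / 3)
  got <- dosurv:::censor_survival(cm, c(1, 3, 5, 7), left = TRUE)
  expect_equal(got, g, tolerance = 1e-12)
  expect_equal(ipcw_c(risk, time, event, cm), 1) # all concordant
  curve <- ipcw_c_curve(risk, time, event, cm, taus = c(3, 5, 7))
  expect_equal(curve$c_index, rep(1, 3))
})

test_that("the Brier score matches its constant-prediction values", {
  time <- c(2, 3, 5, 7, 9, 11)
  event <- rep(1, 6)
  cm <- fit_censoring_model(tibble::tibble(time = time, event = event))
  # no censoring, S(tau) = 1, everyone event-free at tau -> 0
  expect_equal(brier_score(rep(1, 6), time, event, cm, tau = 1), 0)
  # no censoring, S(tau) = 0.5 -> 0.25 regardless of outcomes
  expect_equal(brier_score(rep(0.5, 6), time, event, cm, tau = 6), 0.25)
})

test_that("Brier score and IBS match the Kaplan-Meier-weighted oracle", {
  withr::with_seed(37, {
    for (r in 1:20) {
      d <- random_censored_data(n = 40, cens_frac = 0.35)
      cm <- fit_censoring_model(tibble::tibble(time = d$time,
                                               event = d$event))
      surv <- matrix(runif(40 * 4), 40, 4)
      surv <- t(apply(surv, 1, function(x) sort(x, decreasing = TRUE)))
      grid <- quantile(d$time, c(0.2, 0.4, 0.6, 0.8), names = FALSE)
      grid <- unique(round(grid, 1))
      if (length(grid) < 2) next
      surv <- surv[, seq_along(grid), drop = FALSE]
      for (k in seq_along(grid))
        expect_equal(brier_score(surv[, k], d$time, d$event, cm, grid[k]),
                     oracle_brier(surv[, k], d$time, d$event, grid[k]),
                     tolerance = 1e-6)
      expect_equal(integrated_brier(surv, d$time, d$event, cm, grid),
                   oracle_ibs(surv, d$time, d$event, grid),
                   tolerance = 1e-6)
    }
  })
})

test_that("IBS is a weighted mean of the Brier curve", {
  withr::with_seed(41, {
    d <- random_censored_data(n = 60, cens_frac = 0.3)
    cm <- fit_censoring_model(tibble::tibble(time = d$time,
                                             event = d$event))
    grid <- seq(1, floor(max(d$time)), length.out = 5)
    surv <- matrix(rep(seq(0.9, 0.5, length.out = 5), each = 60), 60)
    bs <- vapply(seq_along(grid), function(k)
      brier_score(surv[, k], d$time, d$event, cm, grid[k]), numeric(1))
    ibs <- integrated_brier(surv, d$time, d$event, cm, grid)
    expect_gte(ibs, min(bs) - 1e-12)
    expect_lte(ibs, max(bs) + 1e-12)
    # a grid reaching past the follow-up is truncated with a warning
    expect_warning(
      integrated_brier(cbind(surv, surv[, 5]), d$time, d$event, cm,
                       c(grid, max(d$time) + 10)),
      "truncated")
  })
})

test_that("covariate-dependent censoring weights flow through the Cox model", {
  withr::with_seed(43, {
    n <- 400
    z <- rbinom(n, 1, 0.5)
    cens <- rexp(n, 0.03 * exp(0.8 * z))
    tev <- rexp(n, 0.02)
    time <- pmin(tev, cens)
    event <- as.integer(tev <= cens)
    covars <- tibble::tibble(z = z)
    cm <- fit_censoring_model(tibble::tibble(time = time, event = event),
                              covars, type = "cox")
    expect_equal(cm$type, "cox")
    expect_gt(cm$coefs[["z"]], 0.3)  # censoring hazard increases with z
    risk <- rnorm(n)
    v <- ipcw_c(risk, time, event, cm, covariates = covars)
    expect_true(is.finite(v))
    # KM fallback when no covariates are available
    cm2 <- fit_censoring_model(tibble::tibble(time = time, event = event),
                               NULL, type = "cox")
    expect_equal(cm2$type, "km")
  })
})

test_that("stratified folds balance events to within one", {
  out <- tibble::tibble(event = c(rep(1, 50), rep(0, 950)),
                        time = runif(1000, 1, 60))
  f <- stratified_kfold(out, k = 5, seed = 3)
  expect_equal(as.integer(table(f[out$event == 1])), rep(10L, 5))
  expect_true(all(abs(table(f) - 200) <= 1))
  expect_identical(f, stratified_kfold(out, k = 5, seed = 3))
  expect_false(identical(f, stratified_kfold(out, k = 5, seed = 4)))
  expect_error(stratified_kfold(tibble::tibble(event = c(1, 0, 0, 0)),
                                k = 5), "at least k")
})

test_that("fold event proportions track the cohort rate at scale", {
  cfg <- cohort_config(n_patients = 7000, seed = 47)
  co <- generate_cohort(cfg, volumes = FALSE)
  f <- stratified_kfold(co$records, k = 5, seed = 1)
  props <- tapply(co$records$event, f, mean)
  expect_true(all(abs(props - mean(co$records$event)) < 0.005))
})

test_that("the rank-sum comparison reproduces exact enumeration", {
  # identical samples: every assignment gives the same statistic
  expect_warning(p <- wilcoxon_compare(rep(0.7, 5), rep(0.7, 5)), "tied")
  expect_equal(p, 1.0)
  # maximal separation at n = 5 vs 5: the smallest attainable two-sided p
  expect_equal(wilcoxon_compare(rep(0.9, 5), rep(0.1, 5)), 2 / choose(10, 5))
  # symmetry
  a <- c(0.71, 0.74, 0.69, 0.80, 0.77)
  b <- c(0.70, 0.75, 0.72, 0.68, 0.73)
  expect_equal(wilcoxon_compare(a, b), wilcoxon_compare(b, a))
  # agreement with wilcox.test exact p when there are no ties
  expect_equal(wilcoxon_compare(a, b),
               wilcox.test(a, b, exact = TRUE)$p.value)
})
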