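# shared simulated training data with two strong signals and noise
sim_survival_data <- function(n, p_noise = 18, beta = c(1.2, 1.0),
                              seed = 1, shape = 2.8, scale = 150) {
  withr::with_seed(seed, {
    x <- matrix(rnorm(n * (length(beta) + p_noise)), n,
                dimnames = list(NULL, sprintf("f%02d",
                                              seq_len(length(beta) +
                                                        p_noise))))
    lp <- as.numeric(x[, seq_along(beta), drop = FALSE] %*% beta)
    tev <- scale * (-log(runif(n)) / exp(lp))^(1 / shape)
    cens <- pmin(runif(n, 2, 60), 60)
    list(x = tibble::as_tibble(x),
         outcomes = tibble::tibble(time = pmin(tev, cens),
                                   event = as.integer(tev <= cens)))
  })
}

test_that("Cox fit recovers a known hazard ratio", {
  withr::with_seed(42, {
    n <- 5000
    z <- rbinom(n, 1, 0.5)
    tev <- 80 * (-log(runif(n)) / exp(log(2) * z))^(1 / 2)
    cens <- runif(n, 5, 100)
    out <- tibble::tibble(time = pmin(tev, cens),
                          event = as.integer(tev <= cens))
    fit <- fit_cox(tibble::tibble(z = z), out)
    hr <- exp(fit$beta[["z"]])
    expect_gt(hr, 1.8)
    expect_lt(hr, 2.2)
    td <- tidy(fit)
    expect_named(td, c("term", "estimate", "hazard_ratio", "std.error",
                       "statistic", "p.value"))
    expect_lt(td$p.value, 1e-6)
    expect_equal(glance(fit)$n_events, sum(out$event))
  })
})

test_that("an outcome-independent covariate gets |z| < 2 in ~95% of fits", {
  withr::with_seed(7, {
    hits <- 0
    for (r in 1:40) {
      n <- 300
      out <- tibble::tibble(time = rexp(n, 0.02) + 1,
                            event = rbinom(n, 1, 0.4))
      fit <- fit_cox(tibble::tibble(x = rnorm(n)), out)
      if (abs(tidy(fit)$statistic) < 2) hits <- hits + 1
    }
    expect_gte(hits, 33)  # ~95% expected under the null
  })
})

test_that("Cox fit rejects degenerate inputs", {
  out <- tibble::tibble(time = c(1, 2, 3, 4), event = c(1, 1, 0, 0))
  expect_error(fit_cox(tibble::tibble(x = rep(1, 4)), out), "constant")
  expect_error(fit_cox(tibble::tibble(x = rnorm(4)),
                       tibble::tibble(time = 1:4, event = c(1, 0, 0, 0))),
               "2 events")
  # perfect separation triggers an explicit error in strict mode
  expect_error(fit_cox(tibble::tibble(x = c(1, 1, 0, 0, 0, 0)),
                       tibble::tibble(time = c(1, 2, 10, 11, 12, 13),
                                      event = c(1, 1, 0, 0, 0, 0))),
               "Cox fit failed")
})

test_that("baseline-only model predicts a common valid survival curve", {
  d <- sim_survival_data(200, seed = 3)
  fit <- fit_cox(d$x[0], d$outcomes)
  expect_length(fit$beta, 0)
  s <- predict_survival(fit, d$x, c(5, 20, 40))
  expect_equal(s[1, ], s[100, ])   # identical for every subject
  expect_true(all(diff(s[1, ]) <= 0))
  expect_true(all(s >= 0 & s <= 1))
  expect_equal(risk_score(fit, d$x), rep(0, 200))
})

test_that("Cox Lasso selects the signal and refits without shrinkage", {
  d <- sim_survival_data(2000, seed = 11)
  fit <- fit_cox_lasso(d$x, d$outcomes, seed = 5)
  expect_true(all(c("f01", "f02") %in% fit$selected_features))
  # refit coefficients must differ from the penalized path coefficients
  expect_gt(abs(fit$beta[["f01"]]), 0.5)  # shrinkage removed
  # survival curves obey the contract
  s <- predict_survival(fit, d$x[1:5, ], 1:60)
  expect_true(all(s >= 0 & s <= 1))
  expect_true(all(apply(s, 1, function(r) all(diff(r) <= 1e-12))))
})

test_that("bootstrap Lasso stability selection finds signal features", {
  d <- sim_survival_data(1500, seed = 21)
  res <- fit_cox_bootstrap_lasso(d$x, d$outcomes, n_boot = 30, seed = 9)
  expect_gte(res$trace$selection_frequency[["f01"]], 0.9)
  expect_gte(res$trace$selection_frequency[["f02"]], 0.9)
  noise <- res$trace$selection_frequency[-(1:2)]
  expect_lt(median(noise), 0.9)
  expect_setequal(res$model$selected_features,
                  names(which(res$trace$selection_frequency >= 0.9)))
  # trace is deterministic under a fixed seed
  res2 <- fit_cox_bootstrap_lasso(d$x, d$outcomes, n_boot = 30, seed = 9)
  expect_identical(res$trace$selection_frequency,
                   res2$trace$selection_frequency)
})

test_that("pure-noise bootstrap Lasso degrades to the baseline model", {
  withr::with_seed(13, {
    n <- 600
    x <- tibble::as_tibble(matrix(rnorm(n * 10), n,
                                  dimnames = list(NULL,
                                                  sprintf("g%02d", 1:10))))
    out <- tibble::tibble(time = rexp(n, 0.03) + 1,
                          event = rbinom(n, 1, 0.2))
    res <- fit_cox_bootstrap_lasso(x, out, n_boot = 25, seed = 2)
    expect_lte(length(res$trace$final_features), 1)
  })
})

test_that("selection frequencies are invariant to row order", {
  d <- sim_survival_data(400, p_noise = 5, seed = 31)
  res1 <- fit_cox_bootstrap_lasso(d$x, d$outcomes, n_boot = 10, seed = 4)
  perm <- withr::with_seed(1, sample(400))
  res2 <- fit_cox_bootstrap_lasso(d$x[perm, ],
                                  d$outcomes[perm, ], n_boot = 10,
                                  seed = 4)
  # bootstrap draws differ, but the frequency scale must agree closely
  expect_equal(res1$trace$selection_frequency["f01"],
               res2$trace$selection_frequency["f01"], tolerance = 0.21)
})

test_that("random survival forest predictions obey the contract", {
  d <- sim_survival_data(600, p_noise = 4, seed = 17)
  fit <- fit_rsf(d$x, d$outcomes,
                 hyperparams = list(num_trees = 100, min_node_size = 15),
                 seed = 8)
  s <- predict_survival(fit, d$x[1:10, ], c(0.5, 1:59))
  expect_true(all(s >= 0 & s <= 1))
  expect_true(all(apply(s, 1, function(r) all(diff(r) <= 1e-12))))
  expect_equal(s[, 1], rep(1, 10), tolerance = 0.2) # S near 1 early on
  expect_length(risk_score(fit, d$x[1:10, ]), 10)
  # deterministic under seed
  fit2 <- fit_rsf(d$x, d$outcomes,
                  hyperparams = list(num_trees = 100, min_node_size = 15),
                  seed = 8)
  expect_identical(risk_score(fit, d$x[1:10, ]),
                   risk_score(fit2, d$x[1:10, ]))
  expect_error(fit_rsf(d$x, d$outcomes,
                       hyperparams = list(num_trees = 0)), "invalid")
})

test_that("permutation importance ranks the driving dose summary first", {
  withr::with_seed(3, {
    n <- 800
    mhd <- pmax(rnorm(n, 5, 4), 0)
    x <- tibble::tibble(mean_heart_dose = mhd, n1 = rnorm(n),
                        n2 = rnorm(n), n3 = rnorm(n))
    tev <- 100 * (-log(runif(n)) / exp(0.25 * mhd))^(1 / 2.8)
    cens <- pmin(runif(n, 2, 60), 60)
    out <- tibble::tibble(time = pmin(tev, cens),
                          event = as.integer(tev <= cens))
    fit <- fit_rsf(x, out,
                   hyperparams = list(num_trees = 200, min_node_size = 10,
                                      splitrule = "extratrees"),
                   seed = 5, importance = "permutation")
    expect_equal(tidy(fit)$term[1], "mean_heart_dose")
  })
})

test_that("out-of-bag error decreases or plateaus with more trees", {
  d <- sim_survival_data(500, p_noise = 3, seed = 23)
  e1 <- fit_rsf(d$x, d$outcomes,
                hyperparams = list(num_trees = 10, splitrule = "extratrees"),
                seed = 3)$training_meta$oob_error
  e2 <- fit_rsf(d$x, d$outcomes,
                hyperparams = list(num_trees = 300,
                                   splitrule = "extratrees"),
                seed = 3)$training_meta$oob_error
  expect_lte(e2, e1 + 0.01)
})

test_that("hyperparameter tuning returns the argmax of the CV C-index", {
  d <- sim_survival_data(500, p_noise = 4, seed = 27)
  one <- tune_hyperparameters("rsf", d$x, d$outcomes,
                              data.frame(num_trees = 50,
                                         min_node_size = 15))
  expect_equal(one$best$num_trees, 50)  # single point returned unchanged
  grid <- data.frame(num_trees = 50, min_node_size = c(5, 15, 50),
                     splitrule = "extratrees",
                     stringsAsFactors = FALSE)
  tuned <- tune_hyperparameters("rsf", d$x, d$outcomes, grid, seed = 6)
  expect_true(tuned$best$min_node_size %in% grid$min_node_size)
  expect_equal(max(tuned$results$cv_c), tuned$cv_c)
  expect_error(tune_hyperparameters("rsf", d$x, d$outcomes,
                                    data.frame()), "empty")
})

test_that("Cox models serialize to JSON with their provenance", {
  d <- withr::local_tempdir()
  dat <- sim_survival_data(300, p_noise = 2, seed = 5)
  fit <- fit_cox(dat$x, dat$outcomes)
  f <- file.path(d, "cox.json")
  write_cox_model(fit, f)
  back <- jsonlite::read_json(f)
  expect_equal(unlist(back$beta), fit$beta, tolerance = 1e-12)
})
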