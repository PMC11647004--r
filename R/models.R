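# The four survival models share one prediction contract: a scalar risk
# score and S(t | X) on any time grid (valid, monotone non-increasing).

as_surv <- function(outcomes) {
  survival::Surv(outcomes$time, outcomes$event)
}

predictor_columns <- function(table) {
  setdiff(names(table)[vapply(table, is.numeric, logical(1))], "patient_id")
}

backtick_formula <- function(lhs, cols, env = parent.frame()) {
  as.formula(paste(lhs, "~", paste0("`", cols, "`", collapse = " + ")),
             env = env)
}

new_cox_fit <- function(beta, baseline, selected, meta = list()) {
  structure(list(beta = beta, baseline = baseline,
                 selected_features = selected, training_meta = meta),
            class = c("cox_fit", "dosurv_model"))
}

# Nelson-Aalen style baseline cumulative hazard at covariate value zero.
cox_baseline <- function(fit) {
  bh <- survival::basehaz(fit, centered = FALSE)
  tibble::tibble(time = bh$time, cumhaz = bh$hazard)
}

null_baseline <- function(outcomes) {
  sf <- survival::survfit(as_surv(outcomes) ~ 1)
  tibble::tibble(time = sf$time, cumhaz = sf$cumhaz)
}

#' Fit a Cox proportional-hazards model
#'
#' Maximizes the Cox partial likelihood (Efron tie handling) and attaches
#' the Breslow baseline cumulative hazard, so the fitted object predicts
#' absolute survival curves \eqn{S(t|X) = \exp(-\Lambda_0(t) e^{\beta'X})}.
#'
#' @param table Feature table (numeric predictor columns; `patient_id`
#'   ignored). An empty column set gives a baseline-only model.
#' @param outcomes Tibble with `time` and `event` (at least 2 events).
#' @param strict Turn non-convergence/separation warnings into errors
#'   (default TRUE).
#' @return A `cox_fit`.
#' @export
fit_cox <- function(table, outcomes, strict = TRUE) {
  cols <- predictor_columns(table)
  if (sum(outcomes$event) < 2)
    stop("need at least 2 events", call. = FALSE)
  if (!length(cols))
    return(new_cox_fit(numeric(0), null_baseline(outcomes), character(0),
                       list(type = "baseline_only")))
  const <- cols[vapply(cols, function(c)
    max(table[[c]]) == min(table[[c]]), logical(1))]
  if (length(const))
    stop("constant column(s): ", paste(const, collapse = ", "),
         call. = FALSE)
  df <- data.frame(table[cols], check.names = FALSE)
  df$.y <- as_surv(outcomes)
  do_fit <- function() survival::coxph(backtick_formula(".y", cols),
                                       data = df, ties = "efron")
  fit <- if (strict) {
    withCallingHandlers(do_fit(), warning = function(w) {
      msg <- conditionMessage(w)
      if (grepl("converge|infinite|singular|beta may be infinite", msg,
                ignore.case = TRUE))
        stop("Cox fit failed: ", msg, call. = FALSE)
      invokeRestart("muffleWarning")
    })
  } else suppressWarnings(do_fit())
  beta <- coef(fit)
  if (anyNA(beta)) {
    if (strict)
      stop("Cox fit failed: singular design (NA coefficients)",
           call. = FALSE)
    # aliased columns: refit on the estimable subset
    keep <- cols[!is.na(beta)]
    refit <- fit_cox(table[keep], outcomes, strict = FALSE)
    refit$training_meta$aliased_dropped <- setdiff(cols, keep)
    return(refit)
  }
  names(beta) <- cols
  new_cox_fit(beta, cox_baseline(fit), cols,
              list(type = "cox", loglik = as.numeric(logLik(fit)),
                   n = nrow(df), n_events = sum(outcomes$event),
                   summary = summary(fit)$coefficients))
}

#' Fit a Cox model with Lasso selection and unpenalized refit
#'
#' Fits the penalized Cox partial-likelihood path, picks the largest penalty
#' whose cross-validated deviance is within one standard error of the
#' minimum (the 1-SE rule), then refits an unpenalized Cox model on the
#' features with non-zero coefficients. An empty selection yields a valid
#' baseline-only model.
#'
#' @inheritParams fit_cox
#' @param cv_folds Folds for the internal penalty cross-validation.
#' @param seed Seed controlling the fold assignment.
#' @return A `cox_fit` whose `selected_features` are the surviving columns.
#' @export
fit_cox_lasso <- function(table, outcomes, cv_folds = 5, seed = 1) {
  cols <- predictor_columns(table)
  if (sum(outcomes$event) < 2)
    stop("need at least 2 events", call. = FALSE)
  x <- as.matrix(table[cols])
  y <- as_surv(outcomes)
  foldid <- with_seed(derive_seed(seed, "lasso-folds"),
                      sample(rep_len(seq_len(cv_folds), nrow(x))))
  # stop the path before the unstable tiny-penalty regime: with ~5% events
  # the small-lambda end routinely fails to converge and is never selected;
  # dfmax additionally bounds the model size by events-per-variable >= 2
  cv <- suppressWarnings(
    glmnet::cv.glmnet(x, y, family = "cox", foldid = foldid,
                      standardize = TRUE, nlambda = 50,
                      lambda.min.ratio = 0.05,
                      dfmax = max(10L, ceiling(sum(outcomes$event) / 2))))
  sel <- selected_at_lambda(cv$glmnet.fit, cv$lambda.1se, cols)
  refit <- fit_cox(table[sel], outcomes, strict = FALSE)
  refit$training_meta <- c(refit$training_meta,
                           list(lambda = cv$lambda.1se, rule = "1se",
                                seed = seed))
  refit$selected_features <- sel
  refit
}

selected_at_lambda <- function(glmnet_fit, lambda, cols) {
  b <- as.matrix(coef(glmnet_fit, s = lambda))
  cols[b[, 1] != 0]
}

#' Cox bootstrap Lasso stability selection
#'
#' Draws `n_boot` bootstrap samples of the training rows. On each, a Cox
#' Lasso path is fitted and the penalty is chosen as the largest one whose
#' selected-feature unpenalized refit is not rejected by a likelihood ratio
#' test (level `lrt_level`, df = difference in feature counts) against the
#' refit at the cross-validated deviance-minimizing penalty; the features
#' selected at that penalty are recorded. After all bootstraps, an
#' unpenalized Cox model is refitted on the whole training set using the
#' features selected in at least `threshold` of the bootstraps.
#'
#' @inheritParams fit_cox_lasso
#' @param n_boot Number of bootstrap samples (default 100).
#' @param threshold Selection-frequency threshold (default 0.9).
#' @param lrt_level Likelihood-ratio test level (default 0.05).
#' @return List with `model` (a `cox_fit`) and `trace` (a
#'   `bootstrap_selection_trace`: per-feature selection frequencies,
#'   threshold, final features, redraw count).
#' @export
fit_cox_bootstrap_lasso <- function(table, outcomes, n_boot = 100,
                                    threshold = 0.9, cv_folds = 5,
                                    lrt_level = 0.05, seed = 1) {
  cols <- predictor_columns(table)
  if (sum(outcomes$event) < 2)
    stop("need at least 2 events", call. = FALSE)
  x <- as.matrix(table[cols])
  y_time <- outcomes$time
  y_event <- outcomes$event
  n <- nrow(x)
  counts <- setNames(numeric(length(cols)), cols)
  redraws <- 0L
  for (b in seq_len(n_boot)) {
    idx <- with_seed(derive_seed(seed, "boot", b), {
      repeat {
        i <- sample.int(n, n, replace = TRUE)
        if (sum(y_event[i]) >= 2) break
        redraws <<- redraws + 1L
      }
      i
    })
    sel <- bootstrap_lasso_selection(
      x[idx, , drop = FALSE],
      tibble::tibble(time = y_time[idx], event = y_event[idx]),
      cols, cv_folds, lrt_level, derive_seed(seed, "bootcv", b))
    counts[sel] <- counts[sel] + 1
  }
  freq <- counts / n_boot
  final <- cols[freq >= threshold]
  model <- fit_cox(table[final], outcomes, strict = FALSE)
  model$selected_features <- final
  model$training_meta <- c(model$training_meta,
                           list(type = "cox_bootstrap_lasso", seed = seed,
                                n_boot = n_boot, threshold = threshold))
  trace <- structure(list(n_bootstraps = n_boot,
                          selection_frequency = freq,
                          frequency_threshold = threshold,
                          final_features = final, redraws = redraws),
                     class = "bootstrap_selection_trace")
  list(model = model, trace = trace)
}

#' @export
print.bootstrap_selection_trace <- function(x, ...) {
  cat(sprintf(paste0("<bootstrap_selection_trace> %d bootstraps, ",
                     "%d feature(s) at frequency >= %.2f\n"),
              x$n_bootstraps, length(x$final_features),
              x$frequency_threshold))
  invisible(x)
}

# One bootstrap replicate: fit the penalized path, anchor at the
# deviance-minimizing penalty lambda* (the smallest penalty of the
# df-bounded path), then take the largest penalty whose selected-feature
# unpenalized refit is not rejected by an LRT against the lambda* refit.
bootstrap_lasso_selection <- function(x, outcomes, cols, cv_folds,
                                      lrt_level, seed) {
  y <- as_surv(outcomes)
  dfmax <- max(10L, ceiling(sum(outcomes$event) / 2))
  path <- suppressWarnings(
    glmnet::glmnet(x, y, family = "cox", standardize = TRUE, nlambda = 30,
                   lambda.min.ratio = 0.05, dfmax = dfmax))
  lambdas <- path$lambda
  i_star <- length(lambdas)
  sel_star <- selected_at_lambda(path, lambdas[i_star], cols)
  ll_star <- refit_loglik(x, outcomes, sel_star)
  if (i_star == 1L) return(sel_star)
  # walk candidates from the largest (sparsest) penalty towards lambda*
  prev_sel <- NULL
  for (i in seq_len(i_star - 1L)) {
    sel <- selected_at_lambda(path, lambdas[i], cols)
    if (!is.null(prev_sel) && identical(sel, prev_sel)) next
    prev_sel <- sel
    df <- length(sel_star) - length(sel)
    ll <- refit_loglik(x, outcomes, sel)
    accept <- if (df <= 0) ll >= ll_star - 1e-8 else
      pchisq(2 * (ll_star - ll), df, lower.tail = FALSE) >= lrt_level
    if (accept) return(sel)
  }
  sel_star
}

refit_loglik <- function(x, outcomes, sel) {
  y <- as_surv(outcomes)
  if (!length(sel)) {
    f <- suppressWarnings(survival::coxph(y ~ 1))
    return(f$loglik[1])
  }
  f <- tryCatch(
    suppressWarnings(survival::coxph(y ~ x[, sel, drop = FALSE],
                                     ties = "efron")),
    error = function(e) NULL)
  if (is.null(f)) return(-Inf)
  f$loglik[length(f$loglik)]
}

#' Fit a random survival forest
#'
#' An ensemble of survival trees with log-rank splitting; each tree learns
#' from a bootstrap of the training rows and a random feature subset, and
#' the ensemble survival curve is the average of the trees' Nelson-Aalen
#' estimates. Deterministic under a fixed seed (single-threaded).
#'
#' @inheritParams fit_cox
#' @param hyperparams List with `num_trees`, `mtry` (NULL for sqrt(p)),
#'   `min_node_size`, and optionally `splitrule` (`"logrank"`, the default
#'   exhaustive log-rank search, or `"extratrees"`, which scores a few
#'   random thresholds per candidate feature with the same log-rank
#'   statistic — orders of magnitude faster on wide feature tables) with
#'   `num_random_splits`.
#' @param seed Integer seed.
#' @param importance `"none"` (default) or `"permutation"`.
#' @return An `rsf_fit`.
#' @export
fit_rsf <- function(table, outcomes,
                    hyperparams = list(num_trees = 500, mtry = NULL,
                                       min_node_size = 15),
                    seed = 1, importance = "none") {
  cols <- predictor_columns(table)
  if (sum(outcomes$event) < 2)
    stop("need at least 2 events", call. = FALSE)
  np <- hyperparams$num_trees %||% 500
  mns <- hyperparams$min_node_size %||% 15
  mtry <- hyperparams$mtry %||% max(1L, floor(sqrt(length(cols))))
  splitrule <- hyperparams$splitrule %||% "logrank"
  nrs <- hyperparams$num_random_splits %||% 5L
  if (np < 1 || mns < 1 || mtry < 1 || mtry > length(cols))
    stop("invalid hyperparameters", call. = FALSE)
  df <- data.frame(table[cols], check.names = FALSE)
  df$.time <- outcomes$time
  df$.event <- outcomes$event
  fit <- ranger::ranger(
    formula = backtick_formula("survival::Surv(.time, .event)", cols),
    data = df, num.trees = np, mtry = mtry, min.node.size = mns,
    splitrule = splitrule,
    num.random.splits = if (splitrule == "extratrees") nrs else 1L,
    seed = seed, num.threads = 1, verbose = FALSE,
    importance = importance, respect.unordered.factors = TRUE)
  structure(list(ranger = fit, feature_names = cols,
                 n_trees = np, mtry = mtry, min_node_size = mns,
                 splitrule = splitrule,
                 training_meta = list(seed = seed,
                                      oob_error = fit$prediction.error)),
            class = c("rsf_fit", "dosurv_model"))
}

#' Predicted survival curves on a time grid
#'
#' @param object A fitted `cox_fit` or `rsf_fit`.
#' @param new_data Feature table with the model's feature columns.
#' @param times Numeric vector of evaluation times (years).
#' @return Matrix `nrow(new_data)` x `length(times)` of S(t | X), bounded in
#'   \[0, 1\] and non-increasing along each row.
#' @export
predict_survival <- function(object, new_data, times) {
  UseMethod("predict_survival")
}

step_lookup <- function(step_times, step_values, times, before = 0) {
  idx <- findInterval(times, step_times)
  c(before, step_values)[idx + 1L]
}

#' @export
predict_survival.cox_fit <- function(object, new_data, times) {
  lp <- risk_score(object, new_data)
  ch <- step_lookup(object$baseline$time, object$baseline$cumhaz, times)
  # cap the linear predictor so exp(lp) stays finite (0 * Inf = NaN when a
  # grid time precedes the first event) without changing any ranking
  elp <- exp(pmin(pmax(lp, -700), 700))
  s <- exp(-outer(elp, ch))
  pmin(pmax(s, 0), 1)
}

#' @export
predict_survival.rsf_fit <- function(object, new_data, times) {
  pr <- predict(object$ranger,
                data = data.frame(new_data[object$feature_names],
                                  check.names = FALSE),
                num.threads = 1)
  st <- pr$unique.death.times
  sv <- pr$survival
  idx <- findInterval(times, st)
  out <- vapply(seq_along(times), function(k) {
    if (idx[k] == 0) rep(1, nrow(sv)) else sv[, idx[k]]
  }, numeric(nrow(sv)))
  matrix(pmin(pmax(out, 0), 1), nrow = nrow(sv))
}

#' Scalar risk score
#'
#' The Cox linear predictor, or for forests the ensemble mortality (sum of
#' the cumulative hazard over the death-time grid). Higher is riskier.
#'
#' @inheritParams predict_survival
#' @return Numeric vector, one score per row of `new_data`.
#' @export
risk_score <- function(object, new_data) {
  UseMethod("risk_score")
}

#' @export
risk_score.cox_fit <- function(object, new_data) {
  if (!length(object$beta)) return(rep(0, nrow(new_data)))
  as.numeric(as.matrix(new_data[names(object$beta)]) %*% object$beta)
}

#' @export
risk_score.rsf_fit <- function(object, new_data) {
  pr <- predict(object$ranger,
                data = data.frame(new_data[object$feature_names],
                                  check.names = FALSE),
                num.threads = 1)
  rowSums(pr$chf)
}

#' Tune hyperparameters by cross-validated concordance
#'
#' Evaluates each grid point with stratified k-fold cross-validation and
#' returns the one with the highest mean Harrell C-index on the held-out
#' folds; ties go to the least complex point (fewest trees, smallest mtry,
#' largest terminal nodes first).
#'
#' @param model_type One of `"cox"`, `"cox_lasso"`, `"cox_bootstrap_lasso"`,
#'   `"rsf"`.
#' @param table,outcomes Training data.
#' @param grid Data frame of hyperparameter combinations (one row each);
#'   NULL or empty rows mean the model has nothing to tune.
#' @param cv_folds,seed Cross-validation controls.
#' @return List with `best` (named list of hyperparameters), `cv_c` (its
#'   mean C-index) and `results` (per-point tibble).
#' @export
tune_hyperparameters <- function(model_type, table, outcomes, grid,
                                 cv_folds = 5, seed = 1) {
  if (is.null(grid) || nrow(grid) == 0)
    stop("empty hyperparameter grid", call. = FALSE)
  if (nrow(grid) == 1)
    return(list(best = as.list(grid[1, , drop = FALSE]), cv_c = NA_real_,
                results = tibble::tibble()))
  ord <- order(grid[["num_trees"]] %||% rep(0, nrow(grid)),
               grid[["mtry"]] %||% rep(0, nrow(grid)),
               -(grid[["min_node_size"]] %||% rep(0, nrow(grid))))
  grid <- grid[ord, , drop = FALSE]
  folds <- stratified_kfold(outcomes, k = cv_folds,
                            seed = derive_seed(seed, "tune"))
  scores <- vapply(seq_len(nrow(grid)), function(g) {
    hp <- as.list(grid[g, , drop = FALSE])
    cs <- vapply(seq_len(cv_folds), function(f) {
      tr <- folds != f
      fit <- tryCatch(
        fit_model(model_type, table[tr, , drop = FALSE],
                  outcomes[tr, , drop = FALSE], hyperparams = hp,
                  seed = derive_seed(seed, "tune-fit", g, f)),
        error = function(e) NULL)
      if (is.null(fit)) return(NA_real_)
      harrell_c(risk_score(fit, table[!tr, , drop = FALSE]),
                outcomes$time[!tr], outcomes$event[!tr])
    }, numeric(1))
    mean(cs, na.rm = TRUE)
  }, numeric(1))
  if (all(is.na(scores))) stop("all grid fits failed", call. = FALSE)
  best <- which.max(scores)  # first max in complexity order
  list(best = as.list(grid[best, , drop = FALSE]), cv_c = scores[best],
       results = dplyr::bind_cols(tibble::as_tibble(grid),
                                  tibble::tibble(cv_c = scores)))
}

# Uniform fitting entry used by tuning, cross-validation and the pipeline.
fit_model <- function(model_type, table, outcomes, hyperparams = list(),
                      seed = 1) {
  switch(model_type,
    cox = fit_cox(table, outcomes, strict = FALSE),
    cox_lasso = fit_cox_lasso(table, outcomes,
                              cv_folds = hyperparams$cv_folds %||% 5,
                              seed = seed),
    cox_bootstrap_lasso =
      fit_cox_bootstrap_lasso(table, outcomes,
                              n_boot = hyperparams$n_boot %||% 100,
                              threshold = hyperparams$threshold %||% 0.9,
                              seed = seed)$model,
    rsf = fit_rsf(table, outcomes, hyperparams = hyperparams, seed = seed),
    stop("unknown model type: ", model_type, call. = FALSE))
}

#' @method tidy cox_fit
#' @export
tidy.cox_fit <- function(x, ...) {
  if (!length(x$beta))
    return(tibble::tibble(term = character(0), estimate = numeric(0),
                          hazard_ratio = numeric(0)))
  sm <- x$training_meta$summary
  tibble::tibble(
    term = names(x$beta),
    estimate = unname(x$beta),
    hazard_ratio = exp(unname(x$beta)),
    std.error = if (!is.null(sm)) unname(sm[, "se(coef)"]) else NA_real_,
    statistic = if (!is.null(sm)) unname(sm[, "z"]) else NA_real_,
    p.value = if (!is.null(sm)) unname(sm[, "Pr(>|z|)"]) else NA_real_)
}

#' @method glance cox_fit
#' @export
glance.cox_fit <- function(x, ...) {
  tibble::tibble(n_features = length(x$beta),
                 n = x$training_meta$n %||% NA_integer_,
                 n_events = x$training_meta$n_events %||% NA_integer_,
                 loglik = x$training_meta$loglik %||% NA_real_)
}

#' @method tidy rsf_fit
#' @export
tidy.rsf_fit <- function(x, ...) {
  imp <- x$ranger$variable.importance
  if (is.null(imp))
    return(tibble::tibble(term = x$feature_names, importance = NA_real_))
  tibble::tibble(term = names(imp), importance = unname(imp)) |>
    dplyr::arrange(dplyr::desc(.data$importance))
}

#' @method glance rsf_fit
#' @export
glance.rsf_fit <- function(x, ...) {
  tibble::tibble(num_trees = x$n_trees, mtry = x$mtry,
                 min_node_size = x$min_node_size,
                 oob_error = x$training_meta$oob_error)
}

#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf("<cox_fit> %d feature(s)\n", length(x$beta)))
  if (length(x$beta)) print(utils::head(tidy(x), 10))
  invisible(x)
}

#' @export
print.rsf_fit <- function(x, ...) {
  cat(sprintf("<rsf_fit> %d trees, mtry %d, min node %d, OOB error %.3f\n",
              x$n_trees, x$mtry, x$min_node_size,
              x$training_meta$oob_error))
  invisible(x)
}

#' Serialize a Cox model to JSON
#'
#' @param model A `cox_fit`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_cox_model <- function(model, path) {
  jsonlite::write_json(
    list(beta = as.list(model$beta),
         baseline = list(time = model$baseline$time,
                         cumhaz = model$baseline$cumhaz),
         selected_features = model$selected_features,
         meta = model$training_meta[setdiff(names(model$training_meta),
                                            "summary")]),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
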