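# Censoring-aware performance metrics. The censoring distribution G is
# represented uniformly as G(t | Z) = exp(-H0(t) * exp(gamma' Z)): a
# Kaplan-Meier fit has gamma empty and H0 = -log(KM), a Cox censoring model
# has Breslow H0 and fitted gamma.

#' Fit a model for the censoring distribution
#'
#' Used to build inverse-probability-of-censoring weights (IPCW). The Cox
#' variant regresses the censoring times on clinical covariates (the weights
#' are then subject-specific); it falls back to Kaplan-Meier if the fit
#' fails or no covariates are given.
#'
#' @param outcomes Tibble with `time` and `event` (the event indicator of
#'   the outcome; censoring is its complement).
#' @param covariates Optional tibble of numeric covariate columns.
#' @param type `"km"` or `"cox"`.
#' @return A `censoring_model`.
#' @export
fit_censoring_model <- function(outcomes, covariates = NULL,
                                type = c("km", "cox")) {
  type <- match.arg(type)
  cens <- 1 - outcomes$event
  if (type == "cox" && !is.null(covariates) && ncol(covariates) > 0) {
    cols <- predictor_columns(covariates)
    cols <- cols[vapply(cols, function(c)
      max(covariates[[c]]) > min(covariates[[c]]), logical(1))]
    if (length(cols)) {
      fit <- tryCatch({
        df <- data.frame(covariates[cols], check.names = FALSE)
        df$.y <- survival::Surv(outcomes$time, cens)
        suppressWarnings(survival::coxph(backtick_formula(".y", cols),
                                         data = df, ties = "efron"))
      }, error = function(e) NULL)
      if (!is.null(fit) && !anyNA(coef(fit))) {
        bh <- survival::basehaz(fit, centered = FALSE)
        return(structure(list(type = "cox", h0_time = bh$time,
                              h0 = bh$hazard,
                              coefs = setNames(coef(fit), cols)),
                         class = "censoring_model"))
      }
    }
  }
  sf <- survival::survfit(survival::Surv(outcomes$time, cens) ~ 1)
  structure(list(type = "km", h0_time = sf$time,
                 h0 = -log(pmax(sf$surv, 0)), coefs = numeric(0)),
            class = "censoring_model")
}

#' @export
print.censoring_model <- function(x, ...) {
  cat(sprintf("<censoring_model> %s, %d step(s)\n", x$type,
              length(x$h0_time)))
  invisible(x)
}

censor_lp <- function(cm, covariates) {
  if (!length(cm$coefs)) return(0)
  as.numeric(as.matrix(covariates[names(cm$coefs)]) %*% cm$coefs)
}

# G(t | Z); `left` gives the left limit G(t-).
censor_survival <- function(cm, times, covariates = NULL, left = FALSE) {
  idx <- findInterval(times, cm$h0_time, left.open = left)
  h0 <- c(0, cm$h0)[idx + 1L]
  lp <- censor_lp(cm, covariates)
  if (length(lp) == 1L && lp == 0) exp(-h0) else exp(-outer(exp(lp), h0))
}

cap_weights <- function(w) {
  finite <- w[is.finite(w)]
  if (!length(finite)) stop("censoring survival is 0 for all needed times",
                            call. = FALSE)
  cap <- stats::quantile(finite, 0.99, names = FALSE, type = 7)
  if (any(!is.finite(w)))
    warning("censoring survival reached 0; weights capped", call. = FALSE)
  pmin(w, cap)
}

#' Harrell's concordance index
#'
#' Fraction of comparable pairs (the earlier subject had an observed event)
#' that the risk score orders correctly; risk ties credit 0.5.
#'
#' @param risk_scores Numeric risk scores (higher = riskier).
#' @param times Observed times.
#' @param events Event indicators (0/1).
#' @return Concordance in \[0, 1\], or NA with a warning when no pair is
#'   comparable.
#' @export
harrell_c <- function(risk_scores, times, events) {
  cw <- concordance_terms(risk_scores, times, events)
  if (sum(cw$den) == 0) {
    warning("no comparable pairs; concordance undefined", call. = FALSE)
    return(NA_real_)
  }
  sum(cw$num) / sum(cw$den)
}

# Per-event-subject concordance numerators/denominators with optional pair
# weights; shared by Harrell, IPCW and truncated variants.
concordance_terms <- function(risk, time, event, wmat = NULL) {
  n <- length(risk)
  ev <- which(event == 1)
  num <- den <- numeric(length(ev))
  for (k in seq_along(ev)) {
    i <- ev[k]
    comp <- (time > time[i]) | (time == time[i] & event == 0)
    comp[i] <- FALSE
    if (!any(comp)) next
    w <- if (is.null(wmat)) rep(1, sum(comp)) else wmat[k, comp]
    conc <- (risk[i] > risk[comp]) + 0.5 * (risk[i] == risk[comp])
    num[k] <- sum(w * conc)
    den[k] <- sum(w)
  }
  list(event_times = time[ev], num = num, den = den)
}

#' IPCW-corrected concordance index
#'
#' Weighted concordance with inverse-probability-of-censoring weights
#' \eqn{1/\hat G(T_i-|Z_i)\hat G(T_i-|Z_j)} (Uno's estimator), optionally
#' bounded at a horizon: with `truncation` = tau, pairs whose event time
#' exceeds tau are discarded, giving the bounded index C_tau. Without
#' censoring all weights are 1 and the index equals [harrell_c()] exactly.
#'
#' @inheritParams harrell_c
#' @param censor_model A [fit_censoring_model()] result, fitted on training
#'   data.
#' @param covariates Covariates for subject-specific weights (Cox censoring
#'   model only).
#' @param truncation Horizon tau in years, or NULL for no truncation.
#' @return Concordance in \[0, 1\] (NA with a warning if undefined).
#' @export
ipcw_c <- function(risk_scores, times, events, censor_model,
                   covariates = NULL, truncation = NULL) {
  curve <- ipcw_c_curve(risk_scores, times, events, censor_model,
                        covariates, taus = truncation %||% Inf)
  curve$c_index[1]
}

#' Bounded IPCW concordance over a grid of horizons
#'
#' @inheritParams ipcw_c
#' @param taus Horizons (years).
#' @return Tibble with `tau` and `c_index` (NA where no pair is usable).
#' @export
ipcw_c_curve <- function(risk_scores, times, events, censor_model,
                         covariates = NULL, taus) {
  ev <- which(events == 1)
  if (!length(ev)) {
    warning("no events; concordance undefined", call. = FALSE)
    return(tibble::tibble(tau = taus, c_index = NA_real_))
  }
  # G(T_i- | Z_i) for event subjects, and G(T_i- | Z_j) for partners
  g_self <- censor_survival(censor_model, times[ev],
                            if (!is.null(covariates))
                              covariates[ev, , drop = FALSE] else NULL,
                            left = TRUE)
  if (is.matrix(g_self)) g_self <- diag(g_self)
  g_cross <- censor_survival(censor_model, times[ev], covariates,
                             left = TRUE)
  if (is.matrix(g_cross)) g_cross <- t(g_cross) else
    g_cross <- matrix(g_cross, nrow = length(ev),
                      ncol = length(times))
  w <- cap_weights(1 / (g_self * g_cross))  # rows: event subjects
  cw <- concordance_terms(risk_scores, times, events, wmat = w)
  c_idx <- vapply(taus, function(tau) {
    use <- cw$event_times <= tau
    if (sum(cw$den[use]) == 0) NA_real_ else
      sum(cw$num[use]) / sum(cw$den[use])
  }, numeric(1))
  if (anyNA(c_idx))
    warning("no comparable pairs below some horizons", call. = FALSE)
  tibble::tibble(tau = taus, c_index = c_idx)
}

#' Brier score at a horizon
#'
#' IPCW-weighted mean squared error between event-free status at tau and
#' the predicted survival probability: subjects with an event by tau
#' contribute \eqn{\hat S(\tau)^2 / \hat G(T-)}, subjects still at risk
#' contribute \eqn{(1-\hat S(\tau))^2 / \hat G(\tau)}, and subjects
#' censored before tau contribute only through the weights.
#'
#' @param surv_predictions Predicted S(tau | X), one value per subject.
#' @inheritParams ipcw_c
#' @param tau Evaluation horizon (years).
#' @return Brier score in \[0, 1\].
#' @export
brier_score <- function(surv_predictions, times, events, censor_model,
                        tau, covariates = NULL) {
  brier_curve(matrix(surv_predictions, ncol = 1), times, events,
              censor_model, tau, covariates)$brier[1]
}

brier_curve <- function(surv_matrix, times, events, censor_model, taus,
                        covariates = NULL) {
  n <- length(times)
  g_self <- censor_survival(censor_model, times, covariates, left = TRUE)
  if (is.matrix(g_self)) g_self <- diag(g_self)
  g_tau <- censor_survival(censor_model, taus, covariates)
  # g_tau: subjects x taus (or vector over taus for KM)
  if (!is.matrix(g_tau)) g_tau <- matrix(g_tau, nrow = n, ncol = length(taus),
                                         byrow = TRUE)
  ev_idx <- which(events == 1)
  w_event <- numeric(n)
  if (length(ev_idx)) w_event[ev_idx] <- cap_weights(1 / g_self[ev_idx])
  bs <- vapply(seq_along(taus), function(k) {
    tau <- taus[k]
    s <- surv_matrix[, k]
    had_event <- times <= tau & events == 1
    at_risk <- times > tau
    w_tau <- numeric(n)
    if (any(at_risk)) w_tau[at_risk] <- cap_weights(1 / g_tau[at_risk, k])
    contrib <- numeric(n)
    contrib[had_event] <- s[had_event]^2 * w_event[had_event]
    contrib[at_risk] <- (1 - s[at_risk])^2 * w_tau[at_risk]
    mean(contrib)
  }, numeric(1))
  tibble::tibble(tau = taus, brier = bs)
}

#' Integrated Brier score
#'
#' Trapezoidal integral of the Brier score over a time grid, normalized by
#' the grid span. Grid points beyond the observed follow-up are dropped
#' with a warning.
#'
#' @param surv_matrix Matrix of predicted survival, subjects x grid times.
#' @inheritParams ipcw_c
#' @param grid Evaluation times (years), strictly increasing.
#' @return Scalar integrated Brier score.
#' @export
integrated_brier <- function(surv_matrix, times, events, censor_model,
                             grid, covariates = NULL) {
  stopifnot(all(diff(grid) > 0))
  keep <- grid <= max(times)
  if (!all(keep)) {
    warning("grid truncated to observed follow-up", call. = FALSE)
    grid <- grid[keep]
    surv_matrix <- surv_matrix[, keep, drop = FALSE]
  }
  if (length(grid) < 2)
    stop("need at least 2 usable grid times", call. = FALSE)
  bc <- brier_curve(surv_matrix, times, events, censor_model, grid,
                    covariates)
  sum(diff(grid) * (head(bc$brier, -1) + bc$brier[-1]) / 2) /
    (max(grid) - min(grid))
}

#' Stratified k-fold assignment for censored outcomes
#'
#' Events and censored subjects are partitioned separately and uniformly at
#' random, so per-fold event counts differ by at most one.
#'
#' @param outcomes Tibble with `event`.
#' @param k Number of folds.
#' @param seed Integer seed.
#' @return Integer fold labels (1..k), one per row.
#' @export
stratified_kfold <- function(outcomes, k = 5, seed = 1) {
  ev <- outcomes$event
  if (sum(ev == 1) < k || sum(ev == 0) < k)
    stop("need at least k events and k censored subjects", call. = FALSE)
  folds <- integer(length(ev))
  with_seed(seed, {
    for (s in c(1, 0)) {
      idx <- sample(which(ev == s))
      folds[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  folds
}

#' Two-sided Wilcoxon rank-sum comparison of fold-wise metrics
#'
#' For the small samples of fold-wise metrics the p-value comes from exact
#' enumeration of the rank-sum distribution (midranks for ties), so tied
#' and degenerate samples are handled exactly; larger samples fall back to
#' the normal approximation. With only 5 folds per arm the smallest
#' attainable two-sided p is 2/choose(10,5), so these p-values are
#' descriptive.
#'
#' @param metric_a,metric_b Numeric vectors (length >= 3 each).
#' @return Two-sided p-value.
#' @export
wilcoxon_compare <- function(metric_a, metric_b) {
  stopifnot(length(metric_a) >= 3, length(metric_b) >= 3)
  pooled <- c(metric_a, metric_b)
  if (max(pooled) == min(pooled)) {
    warning("all values tied; p = 1", call. = FALSE)
    return(1)
  }
  n1 <- length(metric_a)
  n <- length(pooled)
  r <- rank(pooled)
  obs <- sum(r[seq_len(n1)])
  if (n <= 20) {
    combos <- utils::combn(n, n1)
    ws <- colSums(matrix(r[combos], nrow = n1))
    mu <- n1 * (n + 1) / 2
    mean(abs(ws - mu) >= abs(obs - mu) - 1e-9)
  } else {
    suppressWarnings(stats::wilcox.test(metric_a, metric_b,
                                        exact = FALSE)$p.value)
  }
}
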