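#' Screening configuration
#'
#' @param p_threshold Significance level for the diagnosis-indicator
#'   association tests (default 0.01).
#' @param fisher_min_cases Below this count of exposed cases, Fisher's exact
#'   test replaces the Chi-squared test (default 10).
#' @param cluster_distance_threshold Dendrogram cut height on the
#'   1 - Kendall-tau distance (default 0.2, so within-cluster tau >= 0.8).
#' @return A `screening_config` list.
#' @export
screening_config <- function(p_threshold = 0.01, fisher_min_cases = 10,
                             cluster_distance_threshold = 0.2) {
  stopifnot(p_threshold > 0, p_threshold < 1,
            cluster_distance_threshold > 0, cluster_distance_threshold < 1)
  structure(list(p_threshold = p_threshold,
                 fisher_min_cases = fisher_min_cases,
                 cluster_distance_threshold = cluster_distance_threshold),
            class = "screening_config")
}

new_screening_result <- function(kept, dropped = character(0),
                                 clusters = list()) {
  structure(list(kept_columns = kept, dropped = dropped,
                 clusters = clusters),
            class = "screening_result")
}

#' @export
print.screening_result <- function(x, ...) {
  cat(sprintf("<screening_result> %d kept, %d dropped, %d cluster(s)\n",
              length(x$kept_columns), length(x$dropped),
              length(x$clusters)))
  invisible(x)
}

#' Remove constant and duplicate predictor columns
#'
#' Columns with the same value for every patient are dropped, as is the
#' later of any column pair whose sample correlation is exactly 1.
#'
#' @param table Feature table (tibble); non-numeric columns and
#'   `patient_id` are passed through untouched.
#' @return A `screening_result` (`kept_columns`, named `dropped` reasons).
#' @export
drop_degenerate <- function(table) {
  num <- names(table)[vapply(table, is.numeric, logical(1))]
  num <- setdiff(num, "patient_id")
  if (nrow(table) < 2) stop("need at least 2 rows", call. = FALSE)
  dropped <- character(0)
  const <- num[vapply(num, function(c) {
    x <- table[[c]]
    max(x) == min(x)
  }, logical(1))]
  dropped[const] <- "constant"
  alive <- setdiff(num, const)
  if (length(alive) > 1) {
    x <- scale(as.matrix(table[alive]))
    cc <- crossprod(x) / (nrow(x) - 1)
    dup <- character(0)
    for (j in seq_along(alive)[-1]) {
      if (any(cc[seq_len(j - 1), j] >= 1 - 1e-12)) {
        i <- which(cc[seq_len(j - 1), j] >= 1 - 1e-12)[1]
        dup[alive[j]] <- paste0("duplicate of ", alive[i])
      }
    }
    dropped[names(dup)] <- dup
    alive <- setdiff(alive, names(dup))
  }
  new_screening_result(alive, dropped)
}

#' Association screening of diagnosis-group indicators
#'
#' For each binary indicator the 2x2 table against the event indicator is
#' tested: Pearson Chi-squared (no continuity correction), or Fisher's exact
#' test when the exposed-with-event cell holds fewer than
#' `config$fisher_min_cases` cases. Indicators with p below
#' `config$p_threshold` are kept.
#'
#' @param indicators Tibble/data frame of binary indicator columns.
#' @param events Binary event vector.
#' @param config A [screening_config()].
#' @return Tibble with `column`, `test`, `p_value`, `kept`.
#' @export
select_diagnosis_indicators <- function(indicators, events,
                                        config = screening_config()) {
  events <- as.numeric(events)
  if (!all(events %in% c(0, 1)))
    stop("`events` must be binary", call. = FALSE)
  purrr::map_dfr(names(indicators), function(nm) {
    x <- as.numeric(indicators[[nm]])
    if (!all(x %in% c(0, 1)))
      stop("indicator '", nm, "' is not binary", call. = FALSE)
    a <- sum(x == 1 & events == 1)
    tab <- matrix(c(a, sum(x == 1 & events == 0),
                    sum(x == 0 & events == 1), sum(x == 0 & events == 0)),
                  2, 2)
    if (a < config$fisher_min_cases) {
      p <- fisher.test(tab)$p.value
      test <- "fisher"
    } else {
      p <- suppressWarnings(chisq.test(tab, correct = FALSE)$p.value)
      test <- "chi2"
    }
    tibble::tibble(column = nm, test = test, p_value = p,
                   kept = is.finite(p) && p < config$p_threshold)
  })
}

#' Clustering-based redundancy elimination
#'
#' Computes pairwise dissimilarities 1 - Kendall's tau-b between dosiomics
#' columns, cuts a complete-linkage dendrogram at
#' `config$cluster_distance_threshold` (guaranteeing within-cluster tau of
#' at least 1 minus the threshold), and keeps one representative per
#' cluster: the member with the highest hazard ratio in a multivariate Cox
#' model fitted on the standardized cluster members (falling back to
#' univariate Cox fits when the joint fit fails). When columns come from
#' several subparts (`region__...` prefixes), clustering is run within each
#' region separately.
#'
#' @param table Feature table restricted to the dosiomics columns to screen.
#' @param outcomes Tibble with `time` and `event`.
#' @param config A [screening_config()].
#' @param by_region Cluster within each region prefix separately (default).
#' @return A `screening_result` with `clusters` (members + representative).
#' @export
cluster_redundancy_elimination <- function(table, outcomes,
                                           config = screening_config(),
                                           by_region = TRUE) {
  cols <- setdiff(names(table)[vapply(table, is.numeric, logical(1))],
                  "patient_id")
  if (length(cols) < 2)
    return(new_screening_result(cols))
  region_of <- sub("__.*$", "", cols)
  groups <- if (by_region) split(cols, region_of) else list(all = cols)
  kept <- character(0)
  dropped <- character(0)
  clusters <- list()
  for (grp in groups) {
    if (length(grp) < 2) {
      kept <- c(kept, grp)
      next
    }
    x <- as.matrix(table[grp])
    tau <- cpp_kendall_matrix(x)
    d <- 1 - tau
    d[is.na(d)] <- 1
    hc <- hclust(as.dist(d), method = "complete")
    memb <- cutree(hc, h = config$cluster_distance_threshold)
    for (k in sort(unique(memb))) {
      members <- grp[memb == k]
      if (length(members) == 1L) {
        kept <- c(kept, members)
        next
      }
      members <- members[order(members)]
      rep_info <- cluster_representative(table, members, outcomes)
      kept <- c(kept, rep_info$representative)
      losers <- setdiff(members, rep_info$representative)
      dropped[losers] <- paste0("clustered with ", rep_info$representative,
                                if (rep_info$fallback)
                                  " (univariate fallback)" else "")
      clusters[[length(clusters) + 1L]] <-
        list(members = members, representative = rep_info$representative,
             fallback = rep_info$fallback)
    }
  }
  new_screening_result(kept[order(match(kept, cols))], dropped, clusters)
}

# Highest hazard ratio (= largest coefficient) among standardized members of
# a multivariate Cox fit; ties and failures handled deterministically.
cluster_representative <- function(table, members, outcomes) {
  y <- survival::Surv(outcomes$time, outcomes$event)
  x <- scale(as.matrix(table[members]))
  x[!is.finite(x)] <- 0
  beta <- tryCatch({
    fit <- withCallingHandlers(
      survival::coxph(y ~ x, ties = "efron"),
      warning = function(w) stop(conditionMessage(w), call. = FALSE))
    b <- coef(fit)
    if (anyNA(b)) stop("singular fit", call. = FALSE)
    b
  }, error = function(e) NULL)
  fallback <- is.null(beta)
  if (fallback)
    beta <- vapply(seq_along(members), function(j) {
      tryCatch(
        coef(suppressWarnings(survival::coxph(y ~ x[, j],
                                              ties = "efron")))[1],
        error = function(e) -Inf)
    }, numeric(1))
  best <- which(beta == max(beta))[1]  # ties: earliest in canonical order
  list(representative = members[best], fallback = fallback)
}

#' Fit the full screening procedure on a training table
#'
#' Runs, in order: degenerate/duplicate removal over all predictors,
#' association screening of the diagnosis indicators, and (optionally)
#' clustering-based redundancy elimination of the dosiomics columns. The
#' returned object stores the surviving column set and can be applied to any
#' table with [apply_screening()] without recomputing statistics, so no
#' information flows from a test set.
#'
#' @param table Training feature table.
#' @param outcomes Training outcomes tibble (`time`, `event`).
#' @param config A [screening_config()].
#' @param cluster_dosiomics Apply redundancy elimination to the
#'   `firstorder`/texture columns (default FALSE).
#' @return A `screening_result`.
#' @export
screen_predictors <- function(table, outcomes, config = screening_config(),
                              cluster_dosiomics = FALSE) {
  res <- drop_degenerate(table)
  kept <- res$kept_columns
  dropped <- res$dropped
  clusters <- list()
  dx_cols <- grep("^dx_", kept, value = TRUE)
  if (length(dx_cols)) {
    assoc <- select_diagnosis_indicators(table[dx_cols], outcomes$event,
                                         config)
    out <- assoc$column[!assoc$kept]
    dropped[out] <- paste0("association p >= ", config$p_threshold)
    kept <- setdiff(kept, out)
  }
  if (cluster_dosiomics) {
    dos_cols <- grep("__(firstorder|glcm|glrlm|glszm|ngtdm|gldm)__", kept,
                     value = TRUE)
    if (length(dos_cols) >= 2) {
      cl <- cluster_redundancy_elimination(table[dos_cols], outcomes, config)
      dropped[names(cl$dropped)] <- cl$dropped
      kept <- setdiff(kept, names(cl$dropped))
      clusters <- cl$clusters
    }
  }
  new_screening_result(kept, dropped, clusters)
}

#' Apply a fitted screening result to a feature table
#'
#' @param result A `screening_result` from [screen_predictors()].
#' @param table Feature table (train or test).
#' @return The table restricted to `patient_id` (if present) and the kept
#'   columns; nothing is recomputed.
#' @export
apply_screening <- function(result, table) {
  keep <- intersect(c("patient_id", result$kept_columns), names(table))
  table[keep]
}

#' Serialize a screening result to JSON for audit
#'
#' @param result A `screening_result`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_screening_result <- function(result, path) {
  jsonlite::write_json(
    list(kept_columns = result$kept_columns,
         dropped = as.list(result$dropped),
         clusters = result$clusters),
    path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
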