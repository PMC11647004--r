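#' Sum the dose of a multi-session course within a six-month window
#'
#' Voxelwise sum of all sessions whose start offset lies within `window_days`
#' of the first treatment (boundary inclusive); later sessions are left out.
#' Masks are taken from the first session (a single anatomy per patient).
#'
#' @param course An [rt_course()].
#' @param window_days Inclusion window in days after the first session
#'   (default 183, i.e. six months).
#' @return A [dose_volume()] with the summed dose.
#' @export
aggregate_sessions <- function(course, window_days = 183) {
  stopifnot(inherits(course, "rt_course"))
  keep <- course$start_offset_days <= window_days
  keep[1] <- TRUE
  total <- Reduce(`+`, lapply(course$sessions[keep], `[[`, "values"))
  new_dose_volume(total, spacing = course$sessions[[1]]$spacing,
                  masks = course$sessions[[1]]$masks)
}

#' Clip high-dose outliers at an in-mask quantile
#'
#' Computes the empirical `quantile` of the dose over the in-mask voxels of
#' `region` and replaces every in-mask value above it by that threshold;
#' voxels outside the mask are untouched. With the default 0.98 this is
#' thresholding at D2, the dose exceeded by only the hottest 2% of the
#' region. The threshold is the inverse-CDF (order-statistic) quantile, so
#' clipping is exactly idempotent: the clipped distribution's quantile is
#' the threshold itself.
#'
#' @param volume A [dose_volume()].
#' @param region Region whose mask defines both the quantile and the voxels
#'   clipped (default the whole heart, the enclosing region).
#' @param quantile Clipping quantile in (0, 1].
#' @return A new [dose_volume()] with clipped values.
#' @export
clip_outliers <- function(volume, region = "whole_heart", quantile = 0.98) {
  stopifnot(inherits(volume, "dose_volume"),
            quantile > 0, quantile <= 1)
  m <- region_mask(volume, region)
  q <- stats::quantile(volume$values[m], probs = quantile, names = FALSE,
                       type = 1)
  vals <- volume$values
  vals[m & vals > q] <- q
  new_dose_volume(vals, spacing = volume$spacing, masks = volume$masks)
}
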