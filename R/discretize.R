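#' Discretize in-mask doses into fixed-width gray levels
#'
#' Doses inside the region mask are binned with a fixed bin width whose
#' origin tracks the in-mask minimum:
#' `level = floor((dose - min) / bin_width) + 1`, with the maximum dose
#' assigned to the top level. Texture features are therefore invariant to
#' adding a constant dose everywhere.
#'
#' @param volume A [dose_volume()].
#' @param region Region name whose mask defines the voxels to discretize.
#' @param bin_width Bin width in Gy (default 0.5).
#' @return A `discretized_volume`: integer 3D array `levels` (NA outside the
#'   mask), `n_levels`, `bin_width` and `origin` (Gy).
#' @export
#' @examples
#' v <- dose_volume(array(c(0, 0.4, 0.5, 1.2, 0, 0, 0, 0), c(2, 2, 2)),
#'                  masks = list(whole_heart = array(c(rep(TRUE, 4),
#'                                                     rep(FALSE, 4)),
#'                                                   c(2, 2, 2))))
#' d <- discretize(v, "whole_heart")
#' d$n_levels  # 3
discretize <- function(volume, region, bin_width = 0.5) {
  stopifnot(inherits(volume, "dose_volume"))
  if (bin_width <= 0) stop("`bin_width` must be positive", call. = FALSE)
  m <- region_mask(volume, region)
  doses <- volume$values[m]
  origin <- min(doses)
  # floor(.)+1 keeps the level formula consistent when the maximum dose
  # falls exactly on a bin edge (it then occupies its own top level)
  n_levels <- as.integer(floor((max(doses) - origin) / bin_width)) + 1L
  lev <- array(NA_integer_, dim(volume$values))
  raw <- as.integer(floor((doses - origin) / bin_width)) + 1L
  lev[m] <- pmin(raw, n_levels)
  # crop to the mask bounding box: the surrounding out-of-mask space carries
  # no pairs, runs or zones, and the builders scan the whole array
  coords <- arrayInd(which(m), dim(m))
  lo <- apply(coords, 2, min)
  hi <- apply(coords, 2, max)
  lev <- lev[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  structure(list(levels = lev, n_levels = n_levels, bin_width = bin_width,
                 origin = origin, region = region),
            class = "discretized_volume")
}

#' @export
print.discretized_volume <- function(x, ...) {
  cat(sprintf("<discretized_volume> region %s, %d level(s), bin %.3g Gy\n",
              x$region, x$n_levels, x$bin_width))
  invisible(x)
}
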