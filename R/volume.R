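#' Dose volumes and radiotherapy courses
#'
#' A `dose_volume` holds a 3D grid of absorbed dose (Gy) together with the
#' voxel spacing (mm) and a set of binary region masks (whole heart and up to
#' five subparts). An `rt_course` is an ordered list of treatment sessions,
#' each a `dose_volume` on a common grid with a start offset in days.
#'
#' @param values 3D numeric array of absorbed dose in Gy, finite and >= 0.
#' @param spacing Voxel spacing in mm, length 1 (isotropic) or 3.
#' @param masks Named list of logical/0-1 arrays with the same dimensions as
#'   `values`. Names must come from [heart_regions()].
#' @return A `dose_volume` object.
#' @export
#' @examples
#' v <- dose_volume(array(1, c(4, 4, 4)), spacing = 2,
#'                  masks = list(whole_heart = array(TRUE, c(4, 4, 4))))
#' mean_dose(v, "whole_heart")
dose_volume <- function(values, spacing = 2, masks = list()) {
  values <- as.array(values)
  if (length(dim(values)) != 3L)
    stop("`values` must be a 3D array", call. = FALSE)
  if (anyNA(values) || any(!is.finite(values)) || any(values < 0))
    stop("dose values must be finite and non-negative", call. = FALSE)
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("`spacing` must be 1 or 3 positive mm values", call. = FALSE)
  bad <- setdiff(names(masks), heart_regions())
  if (length(bad))
    stop("unknown region name(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  masks <- lapply(masks, function(m) {
    m <- array(as.logical(m), dim(values))
    if (anyNA(m)) stop("masks must be binary", call. = FALSE)
    m
  })
  for (m in masks)
    if (!identical(dim(m), dim(values)))
      stop("mask dimensions must match `values`", call. = FALSE)
  structure(list(values = values, spacing = as.numeric(spacing),
                 masks = masks),
            class = "dose_volume")
}

# Trusted internal constructor: skips validation and mask copying for
# volumes produced by the package itself (generator, preprocessing).
new_dose_volume <- function(values, spacing, masks) {
  structure(list(values = values, spacing = spacing, masks = masks),
            class = "dose_volume")
}

#' Recognised heart region names
#'
#' @return Character vector: the whole heart plus its five subparts.
#' @export
heart_regions <- function() {
  c("whole_heart", "left_atrium", "right_atrium",
    "left_ventricle", "right_ventricle", "myocardium")
}

#' @export
print.dose_volume <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<dose_volume> %dx%dx%d voxels, %.3g mm spacing\n",
              d[1], d[2], d[3], x$spacing[1]))
  cat("  dose range: [", sprintf("%.3g", min(x$values)), ", ",
      sprintf("%.3g", max(x$values)), "] Gy\n", sep = "")
  for (r in names(x$masks))
    cat(sprintf("  mask %-16s %d voxels\n", r, sum(x$masks[[r]])))
  invisible(x)
}

region_mask <- function(volume, region) {
  m <- volume$masks[[region]]
  if (is.null(m))
    stop("volume has no mask for region '", region, "'", call. = FALSE)
  if (!any(m))
    stop("region mask '", region, "' is empty", call. = FALSE)
  m
}

#' @rdname dose_volume
#' @param sessions List of `dose_volume` objects sharing grid and spacing.
#' @param start_offset_days Numeric vector of session start offsets in days;
#'   non-decreasing, first must be 0.
#' @export
rt_course <- function(sessions, start_offset_days) {
  if (!length(sessions)) stop("at least one session required", call. = FALSE)
  if (length(sessions) != length(start_offset_days))
    stop("one offset per session required", call. = FALSE)
  if (start_offset_days[1] != 0 || is.unsorted(start_offset_days))
    stop("offsets must be non-decreasing and start at 0", call. = FALSE)
  d1 <- dim(sessions[[1]]$values)
  for (s in sessions)
    if (!identical(dim(s$values), d1))
      stop("sessions must share a common grid", call. = FALSE)
  structure(list(sessions = sessions,
                 start_offset_days = as.numeric(start_offset_days)),
            class = "rt_course")
}

#' @export
print.rt_course <- function(x, ...) {
  cat(sprintf("<rt_course> %d session(s) at day(s) %s\n",
              length(x$sessions),
              paste(x$start_offset_days, collapse = ", ")))
  invisible(x)
}

#' Read and write dose volumes as NIfTI
#'
#' The dose grid and each region mask are written as separate NIfTI files
#' (`<prefix>_dose.nii`, `<prefix>_mask_<region>.nii`) with the voxel spacing
#' recorded in the header.
#'
#' @param volume A [dose_volume()].
#' @param path Directory to write into (created if missing).
#' @param prefix File-name prefix.
#' @return `write_dose_volume()` returns the written file paths invisibly;
#'   `read_dose_volume()` returns a [dose_volume()].
#' @export
write_dose_volume <- function(volume, path, prefix = "volume") {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  files <- file.path(path, paste0(prefix, "_dose.nii"))
  img <- RNifti::asNifti(volume$values)
  RNifti::pixdim(img) <- volume$spacing
  RNifti::writeNifti(img, files)
  for (r in names(volume$masks)) {
    f <- file.path(path, paste0(prefix, "_mask_", r, ".nii"))
    msk <- RNifti::asNifti(array(as.integer(volume$masks[[r]]),
                                 dim(volume$values)))
    RNifti::pixdim(msk) <- volume$spacing
    RNifti::writeNifti(msk, f)
    files <- c(files, f)
  }
  invisible(files)
}

#' @rdname write_dose_volume
#' @export
read_dose_volume <- function(path, prefix = "volume") {
  dose_file <- file.path(path, paste0(prefix, "_dose.nii"))
  img <- RNifti::readNifti(dose_file)
  spacing <- RNifti::pixdim(img)[1:3]
  masks <- list()
  for (r in heart_regions()) {
    f <- file.path(path, paste0(prefix, "_mask_", r, ".nii"))
    if (file.exists(f))
      masks[[r]] <- array(RNifti::readNifti(f) > 0.5, dim(img))
  }
  dose_volume(array(as.numeric(img), dim(img)), spacing = spacing,
              masks = masks)
}
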