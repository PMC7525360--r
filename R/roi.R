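#' In-plane binary erosion of a mask
#'
#' Slice-by-slice 3x3 box erosion (a 3 x 3 x 1 kernel): a voxel survives
#' only if it and all 8 of its in-plane neighbours are set. No coupling
#' across slices. Used to strip partial-volume gray matter / CSF from the
#' edge of white matter masks.
#'
#' @param mask 3D (or 2D) array; treated as binary (> 0.5).
#' @return integer 0/1 array of the same shape, a subset of the input.
#' @export
erode_inplane <- function(mask) {
  d <- dim(mask)
  if (is.null(d) || !(length(d) %in% c(2L, 3L)))
    stop("mask must be a 2D or 3D array", call. = FALSE)
  if (length(d) == 2L) { mask <- array(mask, c(d, 1L)); d <- dim(mask) }
  m <- array(as.numeric(mask > 0.5), d)
  kern <- EBImage::makeBrush(3, shape = "box")
  out <- array(0, d)
  # zero-pad each slice: voxels beyond the slice edge count as background,
  # so a mask touching the edge is eroded there too
  pad <- matrix(0, d[1] + 2L, d[2] + 2L)
  for (z in seq_len(d[3])) {
    pad[2:(d[1] + 1L), 2:(d[2] + 1L)] <- m[, , z]
    er <- EBImage::erode(pad, kern)
    out[, , z] <- er[2:(d[1] + 1L), 2:(d[2] + 1L)]
  }
  storage.mode(out) <- "integer"
  out
}

#' Normal-appearing white matter ROI construction
#'
#' Intersects a tract ROI with the (eroded) white matter mask, then removes
#' lesion voxels: `roi AND wm AND NOT lesions`. What remains is the
#' normal-appearing white matter portion of the tract.
#'
#' @param roi,wm_eroded,lesions 3D binary arrays on the same grid;
#'   `lesions = NULL` is treated as an empty lesion mask.
#' @return integer 0/1 array. Warns if the result is empty.
#' @export
build_nawm_roi <- function(roi, wm_eroded, lesions = NULL) {
  if (!identical(dim(roi), dim(wm_eroded)))
    stop("roi and wm masks have different shapes: ",
         paste(dim(roi), collapse = "x"), " vs ",
         paste(dim(wm_eroded), collapse = "x"), call. = FALSE)
  check_affine_match(roi, wm_eroded, "roi", "wm")
  if (is.null(lesions)) {
    lesions <- array(0, dim(roi))
  } else {
    if (!identical(dim(roi), dim(lesions)))
      stop("roi and lesion masks have different shapes", call. = FALSE)
    check_affine_match(roi, lesions, "roi", "lesions")
  }
  out <- (roi > 0.5) & (wm_eroded > 0.5) & !(lesions > 0.5)
  if (!any(out))
    warning("NAWM ROI is empty after WM intersection and lesion subtraction",
            call. = FALSE)
  out <- array(as.integer(out), dim(roi))
  out
}

# Compare affines when both arrays carry one (attribute "affine"); silent
# when either array has none.
check_affine_match <- function(a, b, name_a, name_b, tol = 1e-6) {
  aa <- attr(a, "affine"); ab <- attr(b, "affine")
  if (!is.null(aa) && !is.null(ab) && max(abs(aa - ab)) > tol)
    stop(sprintf("affine mismatch between %s and %s masks", name_a, name_b),
         call. = FALSE)
  invisible(TRUE)
}

#' Per-ROI MWF summary and myelin heterogeneity index
#'
#' Summarizes the finite MWF values inside an ROI: voxel count, mean, SD
#' (sample, n-1 denominator) and the myelin heterogeneity index
#' `MHI = SD / mean` (the coefficient of variation of MWF over the ROI;
#' higher means more heterogeneous, i.e. more damaged, myelin). ROIs with
#' fewer than `min_voxels` finite values, or a non-positive mean, yield
#' `NaN` MHI with a warning.
#'
#' @param mwf_map an `mwf_map` from [fit_volume()], or a 3D MWF array.
#' @param roi 3D binary array on the same grid.
#' @param min_voxels minimum finite voxel count for a defined MHI.
#' @param roi_name label carried into the output row.
#' @return one-row data.frame: `roi`, `n_voxels`, `mean_mwf`, `sd_mwf`, `mhi`.
#' @examples
#' m <- array(NaN, c(2, 1, 1)); m[] <- c(0.1, 0.2)
#' r <- array(1L, c(2, 1, 1))
#' compute_mhi(m, r, min_voxels = 2)  # mhi = 0.471405
#' @export
compute_mhi <- function(mwf_map, roi, min_voxels = 50L, roi_name = "roi") {
  mwf <- if (inherits(mwf_map, "mwf_map")) mwf_map$mwf else mwf_map
  if (!identical(dim(mwf), dim(roi)))
    stop("MWF map and ROI mask have different shapes", call. = FALSE)
  vals <- mwf[roi > 0.5]
  vals <- vals[is.finite(vals)]
  n <- length(vals)
  if (n == 0L) {
    warning(sprintf("ROI '%s': no finite MWF voxels; MHI undefined", roi_name),
            call. = FALSE)
    return(data.frame(roi = roi_name, n_voxels = 0L, mean_mwf = NaN,
                      sd_mwf = NaN, mhi = NaN, stringsAsFactors = FALSE))
  }
  mean_mwf <- mean(vals)
  sd_mwf <- if (n >= 2L) stats::sd(vals) else NaN
  mhi <- NaN
  if (n < min_voxels) {
    warning(sprintf("ROI '%s': only %d voxels (< min_voxels = %d); MHI undefined",
                    roi_name, n, min_voxels), call. = FALSE)
  } else if (!is.finite(mean_mwf) || mean_mwf <= 0) {
    warning(sprintf("ROI '%s': non-positive mean MWF; MHI undefined", roi_name),
            call. = FALSE)
  } else {
    mhi <- sd_mwf / mean_mwf
  }
  data.frame(roi = roi_name, n_voxels = n, mean_mwf = mean_mwf,
             sd_mwf = sd_mwf, mhi = mhi, stringsAsFactors = FALSE)
}

#' ROI statistics table for one subject
#'
#' Builds the NAWM version of each ROI (WM intersection after in-plane
#' erosion, lesion subtraction) and computes the MWF summary for each.
#'
#' @param mwf_map an `mwf_map` or 3D MWF array.
#' @param wm 3D binary white matter mask (un-eroded; erosion is applied
#'   here unless `erode = FALSE`).
#' @param rois named list of 3D binary ROI masks.
#' @param lesions optional 3D binary lesion mask (`NULL` = none).
#' @param min_voxels minimum ROI size for a defined MHI.
#' @param erode apply [erode_inplane()] to `wm` first.
#' @param subject_id label prepended to each output row.
#' @return data.frame, one row per ROI: `subject_id`, `roi`, `n_voxels`,
#'   `mean_mwf`, `sd_mwf`, `mhi`.
#' @export
roi_stats <- function(mwf_map, wm, rois, lesions = NULL, min_voxels = 50L,
                      erode = TRUE, subject_id = "subject") {
  if (!is.list(rois) || is.null(names(rois)) || any(names(rois) == ""))
    stop("rois must be a named list of masks", call. = FALSE)
  wm_e <- if (erode) erode_inplane(wm) else array(as.integer(wm > 0.5), dim(wm))
  rows <- lapply(names(rois), function(nm) {
    nawm <- build_nawm_roi(rois[[nm]], wm_e, lesions)
    compute_mhi(mwf_map, nawm, min_voxels = min_voxels, roi_name = nm)
  })
  out <- do.call(rbind, rows)
  cbind(data.frame(subject_id = subject_id, stringsAsFactors = FALSE), out)
}
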