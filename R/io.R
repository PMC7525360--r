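#' Read a NIfTI volume
#'
#' Reads a `.nii`/`.nii.gz` file into a plain numeric array carrying the
#' 4x4 voxel-to-world affine in the `"affine"` attribute.
#'
#' @param path file path.
#' @param expect_dims required dimensionality (e.g. 4 for a multi-echo
#'   volume, 3 for a mask); `NULL` to accept anything.
#' @return numeric array with an `"affine"` attribute.
#' @export
read_nifti_vol <- function(path, expect_dims = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (!is.null(expect_dims) && length(dim(arr)) != expect_dims)
    stop(sprintf("%s is %dD where a %dD volume is required",
                 path, length(dim(arr)), expect_dims), call. = FALSE)
  attr(arr, "affine") <- unclass(RNifti::xform(img))
  arr
}

#' Write a NIfTI volume
#'
#' Writes an array as float32 NIfTI, optionally stamping a voxel-to-world
#' affine (taken from the array's `"affine"` attribute when present).
#'
#' @param volume numeric array (3D or 4D).
#' @param path output path (`.nii` or `.nii.gz`).
#' @param affine optional 4x4 affine; default: the array's attribute, else
#'   identity.
#' @return the path, invisibly.
#' @export
write_nifti_vol <- function(volume, path, affine = NULL) {
  if (is.null(affine)) affine <- attr(volume, "affine")
  arr <- volume
  attributes(arr) <- list(dim = dim(volume))
  img <- RNifti::asNifti(arr)
  if (!is.null(affine))
    RNifti::sform(img) <- structure(affine, code = 2L)
  RNifti::writeNifti(img, path, datatype = "float")
  invisible(path)
}

#' Read a binary mask
#'
#' Reads a 3D NIfTI mask and binarizes it at > 0.5, tolerating interpolated
#' or 0/255-coded masks (with a warning when values other than 0/1 are
#' found).
#'
#' @param path file path.
#' @return integer 0/1 array with an `"affine"` attribute.
#' @export
read_mask <- function(path) {
  arr <- read_nifti_vol(path, expect_dims = 3)
  u <- unique(as.vector(arr))
  if (!all(u %in% c(0, 1)))
    warning(sprintf("mask %s has non-binary values; binarizing at > 0.5", path),
            call. = FALSE)
  out <- array(as.integer(arr > 0.5), dim(arr))
  attr(out, "affine") <- attr(arr, "affine")
  out
}

#' Check that two volumes live on the same grid
#'
#' Errors (naming both files) unless shapes match exactly and affines agree
#' to `tol`. The pipeline performs no resampling: misaligned inputs are
#' refused rather than silently interpolated.
#'
#' @param a,b arrays with `"affine"` attributes (first three dims compared).
#' @param name_a,name_b labels (file names) used in the error message.
#' @param tol affine agreement tolerance.
#' @return `TRUE` invisibly.
#' @export
check_alignment <- function(a, b, name_a = "a", name_b = "b", tol = 1e-6) {
  da <- dim(a)[1:3]; db <- dim(b)[1:3]
  if (!identical(da, db))
    stop(sprintf("grid mismatch: %s is %s but %s is %s", name_a,
                 paste(da, collapse = "x"), name_b, paste(db, collapse = "x")),
         call. = FALSE)
  aa <- attr(a, "affine"); ab <- attr(b, "affine")
  if (!is.null(aa) && !is.null(ab) && max(abs(aa - ab)) > tol)
    stop(sprintf("affine mismatch between %s and %s", name_a, name_b),
         call. = FALSE)
  invisible(TRUE)
}

# CSV with a leading comment line naming the package version, the config
# hash and the units of the value columns; read back with
# read.csv(comment.char = "#").
write_commented_csv <- function(df, path, config_hash = "none",
                                units = "mwf=fraction mhi=dimensionless") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# mwimhi %s config_hash=%s units: %s",
                     as.character(utils::packageVersion("mwimhi")),
                     config_hash, units), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}
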