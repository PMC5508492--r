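#' Masked 4D BOLD image
#'
#' The container every pipeline stage transforms: a real-valued
#' `(nx, ny, nz, T)` voxel array with its grid geometry (voxel size in mm,
#' repetition time in seconds) and a 3D brain mask.
#'
#' @param voxels 4D numeric array `(nx, ny, nz, T)`, all values finite.
#' @param voxel_size_mm Numeric length-3, voxel edge lengths in mm.
#' @param tr_seconds Repetition time in seconds (positive).
#' @param brain_mask 3D logical array matching the spatial dimensions, with
#'   at least one `TRUE` voxel.
#' @return An object of class `image4d`.
#' @export
image4d <- function(voxels, voxel_size_mm = c(3, 3, 3), tr_seconds = 3,
                    brain_mask = NULL) {
  if (length(dim(voxels)) != 4) stop("`voxels` must be a 4D array")
  if (dim(voxels)[4] < 2) stop("`voxels` must have at least 2 frames")
  if (!all(is.finite(voxels))) stop("`voxels` must be finite")
  if (length(voxel_size_mm) != 3 || any(voxel_size_mm <= 0)) {
    stop("`voxel_size_mm` must be 3 positive values")
  }
  if (length(tr_seconds) != 1 || tr_seconds <= 0) {
    stop("`tr_seconds` must be a positive scalar")
  }
  if (is.null(brain_mask)) {
    brain_mask <- apply(voxels != 0, 1:3, any)
  }
  if (!identical(dim(brain_mask), dim(voxels)[1:3])) {
    stop("`brain_mask` shape must equal the spatial shape of `voxels`")
  }
  brain_mask <- array(as.logical(brain_mask), dim(brain_mask))
  if (!any(brain_mask)) stop("`brain_mask` must contain at least one voxel")
  structure(
    list(voxels = voxels, voxel_size_mm = as.numeric(voxel_size_mm),
         tr_seconds = as.numeric(tr_seconds), brain_mask = brain_mask),
    class = "image4d"
  )
}

#' @export
print.image4d <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf(
    "<image4d> %d x %d x %d grid, %d frames, %.1f x %.1f x %.1f mm, TR %.1f s, %d brain voxels\n",
    d[1], d[2], d[3], d[4], x$voxel_size_mm[1], x$voxel_size_mm[2],
    x$voxel_size_mm[3], x$tr_seconds, sum(x$brain_mask)))
  invisible(x)
}

#' @export
dim.image4d <- function(x) dim(x$voxels)

n_frames <- function(img) dim(img$voxels)[4]

#' Extract the in-mask time-by-voxel matrix
#'
#' @param img An [image4d()].
#' @return A `T x V` numeric matrix, one column per in-mask voxel (in
#'   column-major voxel order).
#' @export
as_timeseries_matrix <- function(img) {
  d <- dim(img$voxels)
  flat <- matrix(img$voxels, prod(d[1:3]), d[4])
  t(flat[as.vector(img$brain_mask), , drop = FALSE])
}

# Replace the in-mask series of an image4d with the columns of `mat` (T x V);
# out-of-mask voxels are left untouched.
set_timeseries_matrix <- function(img, mat) {
  d <- dim(img$voxels)
  flat <- matrix(img$voxels, prod(d[1:3]), d[4])
  flat[as.vector(img$brain_mask), ] <- t(mat)
  img$voxels <- array(flat, d)
  img
}

# Map an in-mask vector (length V) back onto the 3D grid (0 elsewhere).
unmask <- function(values, mask, fill = 0) {
  out <- array(fill, dim(mask))
  out[mask] <- values
  out
}

#' Write / read a 4D image as NIfTI
#'
#' The voxel array is stored with its grid spacing and TR in the NIfTI
#' `pixdim`; the brain mask is written alongside as `<stem>_mask.nii` when
#' requested.
#'
#' @param img An [image4d()].
#' @param path Output path (`.nii` or `.nii.gz`).
#' @param write_mask Also write the brain mask next to `path`.
#' @return `path`, invisibly.
#' @export
write_image4d <- function(img, path, write_mask = TRUE) {
  nii <- RNifti::asNifti(img$voxels)
  RNifti::pixdim(nii) <- c(img$voxel_size_mm, img$tr_seconds)
  RNifti::writeNifti(nii, path)
  if (write_mask) {
    mpath <- sub("(\\.nii(\\.gz)?)$", "_mask\\1", path)
    mnii <- RNifti::asNifti(array(as.integer(img$brain_mask),
                                  dim(img$brain_mask)))
    RNifti::pixdim(mnii) <- img$voxel_size_mm
    RNifti::writeNifti(mnii, mpath)
  }
  invisible(path)
}

#' @rdname write_image4d
#' @param mask_path Optional NIfTI path of the brain mask; defaults to the
#'   `<stem>_mask` sibling if present, else the nonzero support of the data.
#' @export
read_image4d <- function(path, mask_path = NULL) {
  nii <- RNifti::readNifti(path)
  arr <- array(as.numeric(nii), dim(nii))
  pd <- RNifti::pixdim(nii)
  if (is.null(mask_path)) {
    cand <- sub("(\\.nii(\\.gz)?)$", "_mask\\1", path)
    if (file.exists(cand)) mask_path <- cand
  }
  mask <- NULL
  if (!is.null(mask_path)) {
    mnii <- RNifti::readNifti(mask_path)
    mask <- array(as.numeric(mnii) > 0, dim(mnii))
  }
  image4d(arr, voxel_size_mm = pd[1:3],
          tr_seconds = if (length(pd) >= 4 && pd[4] > 0) pd[4] else 1,
          brain_mask = mask)
}
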