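# Template-based dual regression: spatial regression of each volume on the
# NOI templates (stage 1), then temporal regression of each voxel on the
# recovered time courses (stage 2), yielding Z-scored connectivity maps.

atlas_matrix <- function(atlas, mask) {
  N <- dim(atlas$templates)[4]
  flat <- matrix(atlas$templates, prod(dim(mask)), N)
  flat[as.vector(mask), , drop = FALSE]
}

#' Stage 1: network time courses from spatial regression
#'
#' Every volume's in-mask voxel vector is regressed on all template maps
#' jointly (columns variance-normalised, intercept included); row `t` of the
#' result holds the fitted template coefficients at time `t`.
#'
#' @param img An [image4d()].
#' @param atlas A `noi_atlas` on the same grid (see [make_noi_atlas()]).
#' @return `T x N` matrix of network time courses (columns named by the
#'   atlas labels).
#' @export
stage1_timecourses <- function(img, atlas) {
  if (!identical(dim(atlas$templates)[1:3], dim(img$voxels)[1:3])) {
    stop("atlas grid does not match the image grid")
  }
  D <- atlas_matrix(atlas, img$brain_mask)
  sdv <- apply(D, 2, stats::sd)
  if (any(sdv == 0)) stop("atlas contains a constant template over the mask")
  D <- sweep(D, 2, sdv, `/`)
  X <- as_timeseries_matrix(img)
  design <- cbind(intercept = 1, D)
  qrD <- qr(design)
  if (qrD$rank < ncol(design)) {
    d <- svd(design, nu = 0, nv = 0)$d
    stop(sprintf("atlas design is rank deficient (condition number %.3g)",
                 if (min(d) > 0) max(d) / min(d) else Inf))
  }
  coef <- qr.coef(qrD, t(X)) # (N + 1) x T
  out <- t(coef[-1, , drop = FALSE])
  colnames(out) <- atlas$labels
  out
}

#' Stage 2: voxelwise Z maps from temporal regression
#'
#' Each in-mask voxel series is regressed on all stage-1 time courses
#' (demeaned, intercept included). The per-regressor t statistic
#' (coefficient over its standard error, `T - N - 1` degrees of freedom) is
#' converted to a Z score through the normal quantile of the t cumulative
#' probability. Parameter-estimate (beta) maps are returned alongside.
#'
#' @param img An [image4d()].
#' @param timecourses `T x N` matrix (full column rank, `T > N + 1`).
#' @return List with `zmaps` and `betas`, both `N x V` over in-mask voxels.
#' @export
stage2_zmaps <- function(img, timecourses) {
  Tn <- n_frames(img)
  N <- ncol(timecourses)
  if (Tn <= N + 1) stop("need T > N + 1 for stage-2 degrees of freedom")
  G <- sweep(timecourses, 2, colMeans(timecourses))
  design <- cbind(1, G)
  qrG <- qr(design)
  if (qrG$rank < ncol(design)) {
    d <- svd(design, nu = 0, nv = 0)$d
    stop(sprintf("stage-2 design is rank deficient (condition number %.3g)",
                 if (min(d) > 0) max(d) / min(d) else Inf))
  }
  X <- as_timeseries_matrix(img)
  coef <- qr.coef(qrG, X) # (N + 1) x V
  fitted <- design %*% coef
  rss <- colSums((X - fitted)^2)
  df <- Tn - N - 1
  sigma2 <- rss / df
  xtx_inv <- chol2inv(chol(crossprod(design)))
  se <- sqrt(outer(diag(xtx_inv), sigma2)) # (N + 1) x V
  tstat <- coef / se
  tstat[!is.finite(tstat)] <- 0
  # numerically stable t -> Z via log tail probabilities
  z <- sign(tstat) * stats::qnorm(
    stats::pt(abs(tstat), df, lower.tail = FALSE, log.p = TRUE),
    lower.tail = FALSE, log.p = TRUE)
  z[!is.finite(z)] <- 0
  list(zmaps = z[-1, , drop = FALSE], betas = coef[-1, , drop = FALSE])
}

#' Template-based dual regression of one subject
#'
#' Stage 1 then stage 2 with the same atlas, so corrected and uncorrected
#' data yield directly comparable maps.
#'
#' @param img An [image4d()].
#' @param atlas A `noi_atlas`.
#' @param subject Optional subject identifier carried in the result.
#' @return An object of class `connectivity_result`: `timecourses` (`T x N`),
#'   `zmaps` and `betas` (`N x V` over in-mask voxels), `labels`, `mask`,
#'   `subject`.
#' @export
template_dual_regression <- function(img, atlas, subject = NA) {
  tc <- stage1_timecourses(img, atlas)
  s2 <- stage2_zmaps(img, tc)
  if (!all(is.finite(s2$zmaps))) stop("non-finite Z maps")
  structure(
    list(timecourses = tc, zmaps = s2$zmaps, betas = s2$betas,
         labels = atlas$labels, mask = img$brain_mask, subject = subject),
    class = "connectivity_result")
}

#' @export
print.connectivity_result <- function(x, ...) {
  cat(sprintf("<connectivity_result> subject %s: %d NOIs, %d frames, %d voxels\n",
              as.character(x$subject), ncol(x$timecourses),
              nrow(x$timecourses), ncol(x$zmaps)))
  invisible(x)
}

#' Write a connectivity result (Z maps as 4D NIfTI + time-course TSV)
#'
#' @param result A `connectivity_result`.
#' @param dir Output directory.
#' @param voxel_size_mm Grid spacing recorded in the NIfTI header.
#' @return `dir`, invisibly.
#' @export
write_connectivity <- function(result, dir, voxel_size_mm = c(3, 3, 3)) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  N <- nrow(result$zmaps)
  arr <- array(0, c(dim(result$mask), N))
  for (i in seq_len(N)) arr[, , , i] <- unmask(result$zmaps[i, ], result$mask)
  nii <- RNifti::asNifti(arr)
  RNifti::pixdim(nii) <- voxel_size_mm
  RNifti::writeNifti(nii, file.path(dir, "zmaps.nii.gz"))
  utils::write.table(result$timecourses, file.path(dir, "timecourses.tsv"),
                     sep = "\t", row.names = FALSE, col.names = TRUE)
  invisible(dir)
}
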