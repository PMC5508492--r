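# Spatial smoothing, discrete-cosine high-pass filtering, and component
# regression (aggressive / non-aggressive), composed into FIX-style and
# AROMA-style pipeline orderings.

#' Gaussian spatial smoothing
#'
#' Separable Gaussian convolution applied to every volume; the kernel SD is
#' `fwhm / (2 sqrt(2 ln 2))` in mm, converted to voxels per axis, truncated
#' at 3 SD and normalised. No renormalisation is applied at the mask
#' boundary (values bleed across it); this is applied identically in every
#' strategy so comparisons stay fair.
#'
#' @param img An [image4d()].
#' @param fwhm_mm Full width at half maximum in mm; 0 is the identity.
#' @return A smoothed [image4d()].
#' @export
gaussian_smooth <- function(img, fwhm_mm = 5) {
  if (fwhm_mm < 0) stop("fwhm must be >= 0")
  if (fwhm_mm == 0) return(img)
  sigma_mm <- fwhm_mm / (2 * sqrt(2 * log(2)))
  arr <- img$voxels
  dm <- dim(arr)
  for (axis in 1:3) {
    sigma_vox <- sigma_mm / img$voxel_size_mm[axis]
    r <- ceiling(3 * sigma_vox)
    if (r < 1) next
    kern <- stats::dnorm(-r:r, sd = sigma_vox)
    kern <- kern / sum(kern)
    n <- dm[axis]
    # banded convolution matrix (zero padding at the edges)
    B <- matrix(0, n, n)
    for (i in seq_along(kern)) {
      off <- i - r - 1L
      idx <- seq_len(n - abs(off))
      if (off >= 0) B[cbind(idx + off, idx)] <- kern[i]
      else B[cbind(idx, idx - off)] <- kern[i]
    }
    perm <- c(axis, setdiff(1:4, axis))
    a <- aperm(arr, perm)
    sh <- dim(a)
    a <- B %*% matrix(a, n)
    dim(a) <- sh
    arr <- aperm(a, order(perm))
  }
  img$voxels <- arr
  img
}

# Orthonormal DCT-II columns spanning frequencies in (0, 1/cutoff_s) Hz.
dct_highpass_basis <- function(n, tr_seconds, cutoff_s) {
  jmax <- ceiling(2 * n * tr_seconds / cutoff_s) - 1
  if (jmax < 1) return(matrix(0, n, 0))
  t <- seq_len(n) - 0.5
  B <- vapply(seq_len(jmax),
              function(j) sqrt(2 / n) * cos(pi * t * j / n), numeric(n))
  matrix(B, n, jmax)
}

#' High-pass temporal filtering by discrete-cosine projection
#'
#' Removes per-voxel fluctuations slower than `1 / cutoff_s` Hz by projecting
#' out an orthonormal DCT basis spanning `[0, 1/cutoff_s)`; the temporal mean
#' is restored afterwards.
#'
#' @param img An [image4d()].
#' @param cutoff_s High-pass cutoff period in seconds (must exceed `2 TR`).
#' @return A filtered [image4d()].
#' @export
highpass_filter <- function(img, cutoff_s = 100) {
  if (cutoff_s <= 2 * img$tr_seconds) {
    stop("cutoff_s must exceed 2 * TR")
  }
  n <- n_frames(img)
  B <- dct_highpass_basis(n, img$tr_seconds, cutoff_s)
  X <- as_timeseries_matrix(img)
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  if (ncol(B) > 0) Xc <- Xc - B %*% (crossprod(B, Xc))
  set_timeseries_matrix(img, sweep(Xc, 2, mu, `+`))
}

# Demeaned time-course design matrix with a rank check.
component_design <- function(decomp) {
  M <- sweep(decomp$timecourses, 2, colMeans(decomp$timecourses))
  qrM <- qr(M)
  if (qrM$rank < ncol(M)) {
    d <- svd(M, nu = 0, nv = 0)$d
    kappa <- if (min(d) > 0) max(d) / min(d) else Inf
    stop(sprintf(
      "component time-course matrix is rank deficient (rank %d of %d, condition number %.3g)",
      qrM$rank, ncol(M), kappa))
  }
  M
}

cleanup_result <- function(cleaned, removed_ids, mode, decomp) {
  structure(
    list(cleaned = cleaned, removed_ids = sort(as.integer(removed_ids)),
         mode = mode, tdof_lost = length(removed_ids),
         tdof_total = n_frames(cleaned), decomp = decomp),
    class = "cleanup_result")
}

#' @export
print.cleanup_result <- function(x, ...) {
  cat(sprintf("<cleanup_result> %s removal of %d/%d components (tDoF lost %d of %d)\n",
              x$mode, x$tdof_lost, n_components(x$decomp), x$tdof_lost,
              x$tdof_total))
  invisible(x)
}

#' Non-aggressive removal of noise components
#'
#' All component time courses (demeaned) are fitted jointly to every in-mask
#' voxel series by least squares, and only the fitted contribution of the
#' noise components is subtracted — removing the variance uniquely
#' attributable to the noise time courses while leaving shared
#' signal-correlated variance intact. Temporal means are preserved.
#'
#' @param img An [image4d()] (the data the decomposition describes).
#' @param decomp A [component_decomposition()].
#' @param noise_ids Integer ids of components to remove (possibly empty).
#' @return A `cleanup_result`: `cleaned` [image4d()], `removed_ids`, `mode`,
#'   `tdof_lost`, `tdof_total`.
#' @export
nonaggressive_clean <- function(img, decomp, noise_ids) {
  noise_ids <- as.integer(noise_ids)
  if (any(noise_ids < 1 | noise_ids > n_components(decomp))) {
    stop("unknown component id in noise_ids")
  }
  if (length(noise_ids) == 0) {
    return(cleanup_result(img, integer(0), "non-aggressive", decomp))
  }
  M <- component_design(decomp)
  X <- as_timeseries_matrix(img)
  beta <- qr.coef(qr(M), X)
  cleaned <- X - M[, noise_ids, drop = FALSE] %*%
    beta[noise_ids, , drop = FALSE]
  cleanup_result(set_timeseries_matrix(img, cleaned), noise_ids,
                 "non-aggressive", decomp)
}

#' Aggressive removal of noise components
#'
#' Residualises every in-mask voxel series against the noise component time
#' courses alone (demeaned), removing all variance they explain — shared or
#' unique. Temporal means are preserved.
#'
#' @inheritParams nonaggressive_clean
#' @return A `cleanup_result`.
#' @export
aggressive_clean <- function(img, decomp, noise_ids) {
  noise_ids <- as.integer(noise_ids)
  if (any(noise_ids < 1 | noise_ids > n_components(decomp))) {
    stop("unknown component id in noise_ids")
  }
  if (length(noise_ids) == 0) {
    return(cleanup_result(img, integer(0), "aggressive", decomp))
  }
  Mn <- component_design(decomp)[, noise_ids, drop = FALSE]
  qrn <- qr(Mn)
  if (qrn$rank < ncol(Mn)) {
    d <- svd(Mn, nu = 0, nv = 0)$d
    stop(sprintf("noise time-course matrix is rank deficient (condition number %.3g)",
                 if (min(d) > 0) max(d) / min(d) else Inf))
  }
  X <- as_timeseries_matrix(img)
  cleaned <- X - Mn %*% qr.coef(qrn, X)
  cleanup_result(set_timeseries_matrix(img, cleaned), noise_ids,
                 "aggressive", decomp)
}

#' Run a full denoising strategy on one subject
#'
#' `fix` ordering: smooth, high-pass, decompose, score in all-noise mode,
#' non-aggressive cleanup. `aroma` ordering: smooth, decompose, score in
#' motion-only mode, non-aggressive cleanup, then high-pass.
#'
#' @param img An [image4d()].
#' @param masks `tissue_masks` on the same grid.
#' @param strategy `"fix"` or `"aroma"`.
#' @param scorer `NULL` for the fixed [noise_score()] weights, an
#'   `ic_scorer` from [train_scorer()], or a function mapping a feature
#'   table to a numeric score vector.
#' @param threshold Score threshold: `score >= threshold` marks a component
#'   for removal.
#' @param fwhm_mm,cutoff_s Smoothing and high-pass parameters.
#' @param k,seed Passed to [decompose()]; alternatively supply `decomp` to
#'   reuse a decomposition (it must describe the pre-processed data).
#' @param decomp Optional [component_decomposition()] to use instead of
#'   running ICA (e.g. a ground-truth wrap).
#' @return A `cleanup_result` with the decomposition, features and scores
#'   attached.
#' @export
run_strategy <- function(img, masks, strategy = c("fix", "aroma"),
                         scorer = NULL, threshold = 20, fwhm_mm = 5,
                         cutoff_s = 100, k = "auto", seed = 1L,
                         decomp = NULL) {
  strategy <- match.arg(strategy)
  mode <- if (strategy == "fix") "all-noise" else "motion-only"
  pre <- gaussian_smooth(img, fwhm_mm)
  if (strategy == "fix") pre <- highpass_filter(pre, cutoff_s)
  if (is.null(decomp)) decomp <- decompose(pre, k = k, seed = seed)
  features <- component_features(decomp, masks)
  scores <- if (is.null(scorer)) {
    noise_score(features, mode = mode)$score
  } else if (inherits(scorer, "ic_scorer")) {
    predict_scores(scorer, features)$score
  } else {
    scorer(features)
  }
  noise_ids <- features$component[scores >= threshold]
  res <- nonaggressive_clean(pre, decomp, noise_ids)
  if (strategy == "aroma") {
    res$cleaned <- highpass_filter(res$cleaned, cutoff_s)
  }
  res$strategy <- strategy
  res$features <- features
  res$scores <- scores
  res$preprocessed <- if (strategy == "aroma") highpass_filter(pre, cutoff_s) else pre
  res
}

#' Write a cleanup result (cleaned NIfTI + JSON sidecar)
#'
#' @param result A `cleanup_result`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_cleanup <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_image4d(result$cleaned, file.path(dir, "cleaned.nii.gz"))
  jsonlite::write_json(
    list(removed_ids = result$removed_ids, mode = result$mode,
         tdof_lost = result$tdof_lost, tdof_total = result$tdof_total),
    file.path(dir, "cleanup.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
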