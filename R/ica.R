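# Single-subject spatial ICA: PCA whitening followed by fixed-point
# negentropy maximisation (tanh contrast, symmetric decorrelation) on the
# spatial dimension, with variance accounting and a matching utility used as
# a test oracle for source recovery.

#' Construct a component decomposition object
#'
#' @param spatial_maps `K x V` matrix of z-scored voxel weights (zero mean,
#'   unit SD over the `V` in-mask voxels).
#' @param timecourses `T x K` matrix of component time courses.
#' @param variance_fraction Length-`K` vector in `[0, 1]`: fraction of the
#'   (voxel- and spatially-demeaned) data variance carried by each component.
#' @param mask 3D logical brain mask with `V` `TRUE` voxels.
#' @param mean_volume Length-`V` voxelwise temporal mean.
#' @param global_tc Length-`T` spatial-mean time course removed before
#'   whitening (kept so back-projection is exact).
#' @param voxel_size_mm,tr_seconds Grid geometry carried along.
#' @return An object of class `component_decomposition`.
#' @export
component_decomposition <- function(spatial_maps, timecourses,
                                    variance_fraction, mask, mean_volume,
                                    global_tc = NULL,
                                    voxel_size_mm = c(3, 3, 3),
                                    tr_seconds = 3) {
  K <- nrow(spatial_maps)
  Tn <- nrow(timecourses)
  stopifnot(ncol(timecourses) == K, length(variance_fraction) == K,
            sum(mask) == ncol(spatial_maps),
            length(mean_volume) == ncol(spatial_maps))
  if (K > Tn - 1) stop("K must be <= T - 1")
  if (!all(is.finite(timecourses))) stop("time courses must be finite")
  if (sum(variance_fraction) > 1 + 1e-6) {
    stop("variance fractions must sum to at most 1")
  }
  structure(
    list(spatial_maps = spatial_maps, timecourses = timecourses,
         variance_fraction = as.numeric(variance_fraction), mask = mask,
         mean_volume = as.numeric(mean_volume),
         global_tc = global_tc %||% rep(0, Tn),
         voxel_size_mm = voxel_size_mm, tr_seconds = tr_seconds),
    class = "component_decomposition")
}

#' @export
print.component_decomposition <- function(x, ...) {
  cat(sprintf("<component_decomposition> %d components, %d frames, %d voxels; variance modelled %.1f%%\n",
              nrow(x$spatial_maps), nrow(x$timecourses),
              ncol(x$spatial_maps), 100 * sum(x$variance_fraction)))
  invisible(x)
}

n_components <- function(decomp) nrow(decomp$spatial_maps)

# 3D volume of one component's spatial map (0 outside the mask).
map_volume <- function(decomp, k) unmask(decomp$spatial_maps[k, ], decomp$mask)

#' Spatial ICA decomposition of a 4D image
#'
#' The in-mask data are voxelwise demeaned, the spatial mean of each volume
#' is removed (and retained as `global_tc`), the result is PCA-whitened and
#' rotated by fixed-point negentropy maximisation with symmetric
#' decorrelation. Components are ordered by descending variance fraction and
#' signed so every spatial map has positive skewness. With `k = "auto"` the
#' dimensionality is the smallest k retaining 95% of the PCA variance,
#' capped at `min(T/2, 60)`.
#'
#' @param img An [image4d()].
#' @param k Number of components, or `"auto"`.
#' @param seed Seed for the ICA initialisation (the decomposition is
#'   deterministic given a seed).
#' @param maxit,tol Fixed-point iteration controls.
#' @return A [component_decomposition()].
#' @export
decompose <- function(img, k = "auto", seed = 1L, maxit = 300, tol = 1e-9) {
  X <- as_timeseries_matrix(img)
  Tn <- nrow(X); Vn <- ncol(X)
  if (!identical(k, "auto")) {
    k <- as.integer(k)
    if (k > Tn - 1) stop("k must be <= T - 1")
    if (k < 1) stop("k must be >= 1")
  }
  mv <- colMeans(X)
  Xc <- sweep(X, 2, mv)
  if (max(abs(Xc)) == 0) stop("degenerate data: zero temporal variance everywhere")
  g <- rowMeans(Xc)
  Xcc <- Xc - g # recycles g down each column (per-row subtraction)

  sv <- svd(Xcc)
  rank <- sum(sv$d > sv$d[1] * 1e-10)
  if (rank == 0) stop("degenerate data: no variance after demeaning")
  if (identical(k, "auto")) {
    vr <- cumsum(sv$d^2) / sum(sv$d^2)
    k <- which(vr >= 0.95)[1]
    k <- min(k, floor(Tn / 2), 60L, rank)
    k <- max(k, 1L)
  } else {
    k <- min(k, rank)
  }

  Z <- t(sv$v[, seq_len(k), drop = FALSE]) * sqrt(Vn) # k x V, ZZ'/V = I
  W <- withr::with_seed(derive_seed(seed, "ica_init"), {
    w0 <- matrix(stats::rnorm(k * k), k, k)
    s0 <- svd(w0)
    s0$u %*% t(s0$v)
  })
  for (it in seq_len(maxit)) {
    WZ <- W %*% Z
    G <- tanh(WZ)
    W1 <- G %*% t(Z) / Vn - diag(rowMeans(1 - G^2), k) %*% W
    s1 <- svd(W1)
    W1 <- s1$u %*% t(s1$v)
    conv <- max(abs(abs(diag(W1 %*% t(W))) - 1))
    W <- W1
    if (conv < tol) break
  }
  S <- W %*% Z                 # k x V, rows zero-mean, unit population SD
  A <- Xcc %*% t(S) / Vn       # T x k least-squares mixing

  # exact rescale to sample-SD z-scored maps
  sdr <- apply(S, 1, stats::sd)
  sdr[sdr == 0] <- 1
  M <- S / sdr
  A <- sweep(A, 2, sdr, `*`)

  vf <- (colSums(A^2) * apply(M, 1, function(r) sum(r^2))) / sum(Xcc^2)

  ord <- order(vf, decreasing = TRUE)
  M <- M[ord, , drop = FALSE]; A <- A[, ord, drop = FALSE]; vf <- vf[ord]
  for (i in seq_len(k)) {
    if (skewness(M[i, ]) < 0) {
      M[i, ] <- -M[i, ]
      A[, i] <- -A[, i]
    }
  }
  component_decomposition(M, A, vf, img$brain_mask, mv, global_tc = g,
                          voxel_size_mm = img$voxel_size_mm,
                          tr_seconds = img$tr_seconds)
}

#' Reconstruct the data modelled by a decomposition
#'
#' `mean_volume + global_tc (x) 1 + timecourses %*% spatial_maps`; on
#' noise-free data of rank k decomposed at k this matches the input to
#' machine precision.
#'
#' @param decomp A [component_decomposition()].
#' @return `T x V` matrix over in-mask voxels.
#' @export
back_project <- function(decomp) {
  rec <- decomp$timecourses %*% decomp$spatial_maps
  rec <- rec + decomp$global_tc # per-row global term
  sweep(rec, 2, decomp$mean_volume, `+`)
}

#' Total variance fraction of a set of components
#'
#' @param decomp A [component_decomposition()].
#' @param component_ids Integer ids (possibly empty).
#' @return Sum of the components' variance fractions, in `[0, 1]`.
#' @export
variance_fraction_of <- function(decomp, component_ids) {
  if (length(component_ids) == 0) return(0)
  ids <- as.integer(component_ids)
  if (any(is.na(ids)) || any(ids < 1) || any(ids > n_components(decomp))) {
    stop("unknown component id")
  }
  sum(decomp$variance_fraction[ids])
}

#' Greedily match components to reference maps by spatial correlation
#'
#' Components are processed in descending variance order; each takes the
#' unclaimed reference with the highest absolute Pearson correlation.
#'
#' @param decomp A [component_decomposition()].
#' @param reference_maps `R x V` matrix over the same in-mask voxels, or a 4D
#'   array on the same grid (one reference per volume).
#' @return A [tibble::tibble()] with columns `component`, `reference`, `r`.
#' @export
match_components <- function(decomp, reference_maps) {
  if (is.array(reference_maps) && length(dim(reference_maps)) == 4) {
    if (!identical(dim(reference_maps)[1:3], dim(decomp$mask))) {
      stop("reference grid does not match the decomposition grid")
    }
    flat <- matrix(reference_maps, prod(dim(decomp$mask)),
                   dim(reference_maps)[4])
    reference_maps <- t(flat[as.vector(decomp$mask), , drop = FALSE])
  }
  if (ncol(reference_maps) != ncol(decomp$spatial_maps)) {
    stop("reference grid does not match the decomposition grid")
  }
  K <- n_components(decomp)
  R <- nrow(reference_maps)
  cors <- abs(stats::cor(t(decomp$spatial_maps), t(reference_maps)))
  cors[!is.finite(cors)] <- 0
  ord <- order(decomp$variance_fraction, decreasing = TRUE)
  taken <- rep(FALSE, R)
  comp <- integer(0); ref <- integer(0); rr <- numeric(0)
  for (i in ord) {
    avail <- which(!taken)
    if (length(avail) == 0) break
    j <- avail[which.max(cors[i, avail])]
    taken[j] <- TRUE
    comp <- c(comp, i); ref <- c(ref, j); rr <- c(rr, cors[i, j])
  }
  o <- order(comp)
  tibble::tibble(component = comp[o], reference = ref[o], r = rr[o])
}

#' Wrap a subject's ground truth as a component decomposition
#'
#' Builds an exact decomposition (true maps and time courses) so classifier
#' and cleanup behaviour can be tested independently of ICA recovery error.
#' Comes with ground-truth labels attached as the `labels` attribute.
#'
#' @param subject A [make_subject()] result.
#' @return A [component_decomposition()]; `attr(, "labels")` holds a label
#'   tibble (`component`, `label`, `subtype`, `provenance`).
#' @export
wrap_ground_truth <- function(subject) {
  img <- subject$image
  tr <- subject$truth
  mask <- img$brain_mask
  ks <- ncol(tr$signal_timecourses)
  kn <- ncol(tr$noise_timecourses)
  K <- ks + kn
  if (K == 0) stop("ground truth has no sources")
  V <- sum(mask)
  Tn <- n_frames(img)
  M <- matrix(0, K, V)
  A <- matrix(0, Tn, K)
  contrib <- numeric(K)
  zrow <- function(m) {
    v <- m[mask]
    s <- stats::sd(v)
    if (s == 0) rep(0, V) else (v - mean(v)) / s
  }
  for (k in seq_len(ks)) {
    M[k, ] <- zrow(tr$signal_maps[, , , k])
    A[, k] <- tr$signal_timecourses[, k]
    contrib[k] <- sum(tr$signal_maps[, , , k][mask]^2) *
      sum(tr$signal_timecourses[, k]^2)
  }
  for (j in seq_len(kn)) {
    M[ks + j, ] <- zrow(tr$noise_maps[, , , j])
    A[, ks + j] <- tr$noise_timecourses[, j]
    contrib[ks + j] <- sum(tr$noise_maps[, , , j][mask]^2) *
      sum(tr$noise_timecourses[, j]^2)
  }
  X <- as_timeseries_matrix(img)
  Xc <- sweep(X, 2, colMeans(X))
  tot <- sum(Xc^2)
  vf <- if (tot > 0) pmin(contrib / max(tot, sum(contrib)), 1) else rep(0, K)
  labels <- tibble::tibble(
    component = seq_len(K),
    label = c(rep("signal", ks), rep("noise", kn)),
    subtype = c(rep(NA_character_, ks), tr$subtype),
    provenance = "ground-truth")
  d <- component_decomposition(M, A, vf, mask, colMeans(X),
                               voxel_size_mm = img$voxel_size_mm,
                               tr_seconds = img$tr_seconds)
  attr(d, "labels") <- labels
  d
}

#' Write a decomposition to disk (NIfTI maps + TSV tables)
#'
#' @param decomp A [component_decomposition()].
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_decomposition <- function(decomp, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  K <- n_components(decomp)
  arr <- array(0, c(dim(decomp$mask), K))
  for (k in seq_len(K)) arr[, , , k] <- map_volume(decomp, k)
  nii <- RNifti::asNifti(arr)
  RNifti::pixdim(nii) <- decomp$voxel_size_mm
  RNifti::writeNifti(nii, file.path(dir, "spatial_maps.nii.gz"))
  utils::write.table(decomp$timecourses, file.path(dir, "timecourses.tsv"),
                     sep = "\t", row.names = FALSE,
                     col.names = sprintf("IC%02d", seq_len(K)))
  utils::write.table(
    data.frame(component = seq_len(K),
               variance_fraction = decomp$variance_fraction),
    file.path(dir, "variance_fractions.tsv"),
    sep = "\t", row.names = FALSE, col.names = TRUE)
  invisible(dir)
}
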