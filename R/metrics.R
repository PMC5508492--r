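# Evaluation metrics: RSN identifiability, split-half pseudo-Z
# reproducibility, tDoF loss, %dSTD maps with permutation group tests and
# probability maps, |%dZ| with ANOVA and paired tests, TFCE, grayplots.

#' RSN identifiability of a subject-level Z map
#'
#' Ratio of the mean absolute Z inside the RSN mask (template thresholded at
#' `|Z| > mask_threshold`) to the mean absolute Z outside it, both restricted
#' to the brain domain. A ratio above 1 indicates an identifiable network.
#'
#' @param zmap 3D Z-score array, or a length-`V` in-mask vector.
#' @param template 3D template array (Z-valued), or in-mask vector.
#' @param mask_threshold RSN mask threshold on `|template|` (1.5, 2.3 or 3.1
#'   in the sensitivity range; default 2.3).
#' @param domain_mask 3D logical brain domain (required when vectors are
#'   supplied it must be the matching mask).
#' @return The identifiability ratio (positive scalar).
#' @export
rsn_identifiability <- function(zmap, template, mask_threshold = 2.3,
                                domain_mask = NULL) {
  if (is.array(zmap) && length(dim(zmap)) == 3) {
    if (is.null(domain_mask)) domain_mask <- array(TRUE, dim(zmap))
    z <- zmap[domain_mask]
    tp <- template[domain_mask]
  } else {
    z <- as.numeric(zmap)
    tp <- as.numeric(template)
  }
  if (length(z) != length(tp)) stop("zmap and template must share a grid")
  inside <- abs(tp) > mask_threshold
  if (!any(inside)) stop("RSN mask is empty at this threshold")
  if (all(inside)) stop("outside set is empty at this threshold")
  denom <- mean(abs(z[!inside]))
  if (denom == 0) stop("zero mean |Z| outside the mask: ratio undefined")
  mean(abs(z[inside])) / denom
}

#' Split-half reproducibility of group-level network maps
#'
#' For each random split of the cohort into two equal halves, group-mean
#' stage-2 parameter-estimate maps are computed per NOI per half (restricted
#' to gray matter), the `N x N` between-half spatial correlation matrix is
#' formed, and each diagonal entry is standardised against the pooled
#' off-diagonal null to a pseudo-Z. Means and SDs over splits are returned.
#'
#' @param results List of `connectivity_result`s (>= 4 subjects; an odd
#'   count is trimmed to the largest even subset with a message).
#' @param gray_matter 3D gray-matter probability map (used at > 0.5).
#' @param n_splits Number of random splits.
#' @param seed Seed for the split sequence.
#' @param use `"betas"` (parameter estimates, default) or `"zmaps"`.
#' @param fisher Apply Fisher's z-transform to the correlations before
#'   standardising.
#' @return A tibble of class `reproducibility_result` with columns `noi`,
#'   `mean_pseudo_z`, `sd_pseudo_z`, plus `n_splits`/`seed` attributes.
#' @export
split_half_reproducibility <- function(results, gray_matter, n_splits = 500,
                                       seed = 1L, use = c("betas", "zmaps"),
                                       fisher = FALSE) {
  use <- match.arg(use)
  n <- length(results)
  if (n < 4) stop("split-half reproducibility needs at least 4 subjects")
  if (n %% 2 == 1) {
    message("odd cohort size; using the largest even subset (", n - 1,
            " subjects)")
    n <- n - 1
    results <- results[seq_len(n)]
  }
  mask <- results[[1]]$mask
  gm <- (gray_matter > 0.5)[mask]
  if (!any(gm)) stop("gray-matter mask is empty")
  maps <- lapply(results, function(r) r[[use]][, gm, drop = FALSE])
  N <- nrow(maps[[1]])
  drop_noi <- which(vapply(seq_len(N), function(i) {
    any(vapply(maps, function(m) stats::sd(m[i, ]) == 0, logical(1)))
  }, logical(1)))
  keep <- setdiff(seq_len(N), drop_noi)
  if (length(drop_noi) > 0) {
    message("excluding zero-variance NOI(s): ", paste(drop_noi, collapse = ", "))
  }
  if (length(keep) < 2) stop("need at least 2 usable NOIs")
  pz <- matrix(NA_real_, n_splits, N)
  withr::with_seed(derive_seed(seed, "splits"), {
    for (s in seq_len(n_splits)) {
      perm <- sample.int(n)
      h1 <- perm[seq_len(n / 2)]
      h2 <- perm[(n / 2 + 1):n]
      g1 <- Reduce(`+`, maps[h1]) / length(h1)
      g2 <- Reduce(`+`, maps[h2]) / length(h2)
      C <- stats::cor(t(g1[keep, , drop = FALSE]), t(g2[keep, , drop = FALSE]))
      if (fisher) C <- atanh(pmin(pmax(C, -1 + 1e-12), 1 - 1e-12))
      off <- C[row(C) != col(C)]
      mu <- mean(off); sdo <- stats::sd(off)
      if (sdo == 0) next
      pz[s, keep] <- (diag(C) - mu) / sdo
    }
  })
  out <- tibble::tibble(
    noi = seq_len(N),
    label = results[[1]]$labels %||% as.character(seq_len(N)),
    mean_pseudo_z = colMeans(pz, na.rm = TRUE),
    sd_pseudo_z = apply(pz, 2, stats::sd, na.rm = TRUE))
  out$mean_pseudo_z[drop_noi] <- NA_real_
  out$sd_pseudo_z[drop_noi] <- NA_real_
  class(out) <- c("reproducibility_result", class(out))
  attr(out, "n_splits") <- n_splits
  attr(out, "seed") <- seed
  attr(out, "excluded_nois") <- drop_noi
  out
}

#' Percent loss in temporal degrees of freedom
#'
#' Every removed component counts as one lost tDoF out of the number of
#' acquired volumes.
#'
#' @param n_removed Number of removed components.
#' @param n_volumes Number of volumes T.
#' @return `100 * n_removed / n_volumes`.
#' @export
tdof_loss_percent <- function(n_removed, n_volumes) {
  if (n_removed < 0 || n_volumes <= 0 || n_removed > n_volumes) {
    stop("need 0 <= n_removed <= n_volumes")
  }
  100 * n_removed / n_volumes
}

#' Voxelwise percent reduction in temporal SD
#'
#' `100 * (SD_original - SD_corrected) / SD_original` over in-mask voxels
#' with positive original SD; other voxels are `NA`.
#'
#' @param original,corrected [image4d()]s on the same grid with the same T.
#' @return 3D array of class `delta_std_map` (percent; `NA` where undefined),
#'   with the brain mask attached.
#' @export
delta_std_map <- function(original, corrected) {
  if (!identical(dim(original$voxels), dim(corrected$voxels)) ||
      !identical(original$brain_mask, corrected$brain_mask)) {
    stop("original and corrected images must share grid, T and mask")
  }
  Xo <- as_timeseries_matrix(original)
  Xc <- as_timeseries_matrix(corrected)
  so <- apply(Xo, 2, stats::sd)
  sc <- apply(Xc, 2, stats::sd)
  val <- ifelse(so > 0, 100 * (so - sc) / so, NA_real_)
  out <- unmask(val, original$brain_mask, fill = NA_real_)
  structure(out, class = "delta_std_map", mask = original$brain_mask)
}

#' Threshold-free cluster enhancement
#'
#' For each voxel with positive statistic value `v`, sums
#' `extent(h)^E * h^H * dh` over thresholds `h = dh, 2 dh, ... <= v`, where
#' `extent(h)` is the size of the connected suprathreshold component
#' containing the voxel. Non-positive voxels map to 0.
#'
#' @param stat_map 3D statistic array.
#' @param E,H Extent and height exponents.
#' @param dh Threshold step (default: max / 100).
#' @param connectivity 26 or 6.
#' @return Enhanced 3D array.
#' @export
tfce <- function(stat_map, E = 0.5, H = 2, dh = NULL, connectivity = 26) {
  mx <- max(stat_map)
  out <- array(0, dim(stat_map))
  if (mx <= 0) return(out)
  if (is.null(dh)) dh <- mx / 100
  if (dh <= 0) stop("dh must be positive")
  for (h in seq(dh, mx, by = dh)) {
    supra <- stat_map >= h
    if (!any(supra)) break
    lab <- label_components(supra, connectivity)
    sizes <- tabulate(lab[supra])
    out[supra] <- out[supra] + sizes[lab[supra]]^E * h^H * dh
  }
  out
}

#' Group test: is %dSTD higher than a floor?
#'
#' Voxelwise one-sample t test of `map - floor_percent > 0` with family-wise
#' error control by sign-flip permutation of the maximum statistic
#' (optionally TFCE-enhanced).
#'
#' @param maps List of `delta_std_map`s (>= 4).
#' @param floor_percent Null floor (the study sweeps 35, 45, 55, 65).
#' @param n_perm Number of sign-flip permutations (>= 100).
#' @param alpha Family-wise significance level.
#' @param use_tfce Enhance the t map with [tfce()] before taking maxima.
#' @param seed Permutation seed.
#' @return List: `stat_map` (t or TFCE-enhanced t), `p_map` (FWE-corrected,
#'   `NA` outside the common defined domain), `sig_mask`, `n_perm`.
#' @export
delta_std_group_test <- function(maps, floor_percent = 35, n_perm = 1000,
                                 alpha = 0.01, use_tfce = TRUE, seed = 1L) {
  if (length(maps) < 4) stop("group test needs at least 4 maps")
  if (n_perm < 100) stop("need n_perm >= 100")
  arr <- simplify2array(lapply(maps, identity)) # nx x ny x nz x S
  S <- dim(arr)[4]
  defined <- apply(is.finite(arr), 1:3, all)
  flat <- matrix(arr, ncol = S)[as.vector(defined), , drop = FALSE] -
    floor_percent
  tmap_of <- function(M) {
    mu <- rowMeans(M)
    se <- apply(M, 1, stats::sd) / sqrt(S)
    tv <- ifelse(se > 0, mu / se, 0)
    tv
  }
  enhance <- function(tv) {
    if (!use_tfce) return(tv)
    as.vector(tfce(unmask(pmax(tv, 0), defined))[defined])
  }
  obs <- enhance(tmap_of(flat))
  exceed <- rep(0L, length(obs))
  withr::with_seed(derive_seed(seed, "perm"), {
    for (p in seq_len(n_perm)) {
      flips <- sample(c(-1, 1), S, replace = TRUE)
      mx <- max(enhance(tmap_of(sweep(flat, 2, flips, `*`))))
      exceed <- exceed + (mx >= obs)
    }
  })
  pvals <- (1 + exceed) / (n_perm + 1)
  p_map <- unmask(pvals, defined, fill = NA_real_)
  stat_map <- unmask(obs, defined, fill = 0)
  sig <- defined & (p_map < alpha) & (stat_map > 0)
  sig[is.na(sig)] <- FALSE
  list(stat_map = stat_map, p_map = p_map, sig_mask = sig, n_perm = n_perm)
}

#' Probability map of %dSTD exceeding a threshold
#'
#' Voxelwise fraction of subjects whose %dSTD exceeds `threshold_percent`.
#'
#' @param maps List of `delta_std_map`s (>= 1).
#' @param threshold_percent Binarisation threshold.
#' @return 3D array of fractions in `[0, 1]` (`NA` treated as not exceeding).
#' @export
delta_std_probability_map <- function(maps, threshold_percent = 25) {
  if (length(maps) < 1) stop("need at least one map")
  arr <- simplify2array(lapply(maps, identity))
  if (length(dim(arr)) == 3) dim(arr) <- c(dim(arr), 1)
  exceed <- (arr > threshold_percent) & !is.na(arr)
  apply(exceed, 1:3, mean)
}

#' Percent absolute change in summed Z within an NOI mask
#'
#' `|100 * (sum Z_corrected - sum Z_original) / sum Z_original|`, sums taken
#' over the NOI template mask.
#'
#' @param z_original,z_corrected Z maps (3D arrays or in-mask vectors).
#' @param noi_mask Logical mask (same representation).
#' @return Non-negative percent change.
#' @export
percent_delta_z <- function(z_original, z_corrected, noi_mask) {
  zo <- as.vector(z_original)[as.vector(noi_mask)]
  zc <- as.vector(z_corrected)[as.vector(noi_mask)]
  if (length(zo) == 0) stop("empty NOI mask")
  so <- sum(zo)
  if (so == 0) stop("summed original Z is zero: %dZ undefined for this NOI")
  abs(100 * (sum(zc) - so) / so)
}

#' One-way ANOVA of a metric across NOIs
#'
#' Groups are the NOI columns; pairwise two-sample comparisons are
#' Bonferroni-adjusted. With all values identical the F statistic is 0 and
#' p is 1 (the degenerate 0/0 case is resolved to "no evidence").
#'
#' @param values Numeric `subject x NOI` matrix (>= 2 subjects, >= 2 NOIs).
#' @return List: `f`, `p`, `pairwise` (tibble with Bonferroni-adjusted p).
#' @export
anova_across_nois <- function(values) {
  values <- as.matrix(values)
  if (ncol(values) < 2 || nrow(values) < 2) {
    stop("need >= 2 NOIs and >= 2 subjects")
  }
  if (any(!is.finite(values))) stop("values must be finite")
  y <- as.vector(values)
  g <- factor(rep(seq_len(ncol(values)), each = nrow(values)))
  if (stats::sd(y) == 0) {
    f <- 0; p <- 1
  } else {
    fit <- stats::aov(y ~ g)
    s <- summary(fit)[[1]]
    f <- s[["F value"]][1]
    p <- s[["Pr(>F)"]][1]
  }
  pairs <- utils::combn(ncol(values), 2)
  m <- ncol(pairs)
  pw <- lapply(seq_len(m), function(i) {
    a <- values[, pairs[1, i]]; b <- values[, pairs[2, i]]
    praw <- if (stats::sd(c(a, b)) == 0) 1 else {
      stats::t.test(a, b)$p.value
    }
    tibble::tibble(noi_a = pairs[1, i], noi_b = pairs[2, i], p_raw = praw,
                   p_adj = min(praw * m, 1))
  })
  list(f = f, p = p, pairwise = do.call(rbind, pw))
}

#' Paired t test between two strategies
#'
#' @param a,b Per-subject values (equal length >= 2, non-degenerate paired
#'   differences).
#' @return List with `t` and two-sided `p`.
#' @export
paired_ttest <- function(a, b) {
  if (length(a) != length(b) || length(a) < 2) {
    stop("a and b must have equal length >= 2")
  }
  d <- a - b
  if (stats::sd(d) == 0 && all(d == 0)) return(list(t = 0, p = 1))
  if (stats::sd(d) == 0) stop("zero variance of paired differences")
  r <- stats::t.test(a, b, paired = TRUE)
  list(t = unname(r$statistic), p = r$p.value)
}

#' Grayplot matrix of a scan
#'
#' Voxels-by-time heatmap matrix: gray-matter rows (probability > 0.5) first,
#' then white-matter rows, ordered within tissue by voxel index; every row is
#' demeaned and scaled to unit SD (constant rows become zeros).
#'
#' @param img An [image4d()].
#' @param masks `tissue_masks` on the same grid.
#' @return Matrix of class `grayplot_matrix` with `n_gray` / `n_white`
#'   attributes; see [autoplot.grayplot_matrix()] for rendering.
#' @export
grayplot <- function(img, masks) {
  gm <- masks$gray > 0.5 & img$brain_mask
  wm <- masks$white > 0.5 & img$brain_mask
  if (!any(gm) || !any(wm)) stop("gray and white masks must be non-empty")
  d <- dim(img$voxels)
  flat <- matrix(img$voxels, prod(d[1:3]), d[4])
  rows <- rbind(flat[as.vector(gm), , drop = FALSE],
                flat[as.vector(wm), , drop = FALSE])
  mu <- rowMeans(rows)
  sdv <- apply(rows, 1, stats::sd)
  rows <- (rows - mu) / ifelse(sdv > 0, sdv, 1)
  rows[sdv == 0, ] <- 0
  structure(rows, class = c("grayplot_matrix", "matrix"),
            n_gray = sum(gm), n_white = sum(wm))
}
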