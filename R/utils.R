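# Internal helpers shared across modules: deterministic seed streams,
# array shifting, morphology and connected-component labelling on 3D grids.

#' Derive a reproducible sub-seed from a master seed
#'
#' All randomness in the package flows from one master seed through named
#' substreams so that stages (simulation, ICA initialisation, group splits,
#' permutations) are independently reproducible.
#'
#' @param seed Master seed (integer-like).
#' @param ... Stream identifiers: character strings and/or integers.
#' @return A single integer in `[0, 2^31 - 2]`.
#' @keywords internal
derive_seed <- function(seed, ...) {
  m <- 2147483647 # 2^31 - 1, prime
  h <- as.double(seed) %% m
  for (part in list(...)) {
    codes <- if (is.character(part)) utf8ToInt(part) else as.double(part)
    for (k in codes) h <- (h * 69069 + k + 1) %% m
  }
  as.integer(h %% (m - 1))
}

# Shift a 3D array by integer offsets d = c(dx, dy, dz), padding with `fill`:
# out[i, j, k] = a[i - dx, j - dy, k - dz] where defined.
shift3 <- function(a, d, fill = 0) {
  dm <- dim(a)
  out <- array(fill, dm)
  t1 <- max(1L, 1L + d[1]):min(dm[1], dm[1] + d[1])
  t2 <- max(1L, 1L + d[2]):min(dm[2], dm[2] + d[2])
  t3 <- max(1L, 1L + d[3]):min(dm[3], dm[3] + d[3])
  if (length(t1) < 1 || length(t2) < 1 || length(t3) < 1) return(out)
  out[t1, t2, t3] <- a[t1 - d[1], t2 - d[2], t3 - d[3]]
  out
}

# Offsets of the 26-neighbourhood (or 6-neighbourhood).
neighbour_offsets <- function(connectivity = 26) {
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  g <- g[rowSums(abs(g)) > 0, , drop = FALSE]
  if (connectivity == 6) g <- g[rowSums(abs(g)) == 1, , drop = FALSE]
  g
}

#' Label connected components of a 3D logical mask
#'
#' Iterative minimum-label propagation over the chosen neighbourhood; the
#' grids handled here are small enough that this vectorised pure-R scheme is
#' fast in practice.
#'
#' @param mask 3D logical array.
#' @param connectivity 26 (vertex/edge/face neighbours) or 6 (face only).
#' @return Integer array of the same shape: 0 outside the mask, components
#'   labelled 1..n in arbitrary order.
#' @keywords internal
label_components <- function(mask, connectivity = 26) {
  stopifnot(length(dim(mask)) == 3)
  if (!any(mask)) return(array(0L, dim(mask)))
  offs <- neighbour_offsets(connectivity)
  lab <- array(Inf, dim(mask))
  lab[mask] <- seq_len(sum(mask))
  repeat {
    new <- lab
    for (s in seq_len(nrow(offs))) {
      new <- pmin(new, shift3(new, offs[s, ], fill = Inf))
    }
    new[!mask] <- Inf
    if (identical(new, lab)) break
    lab <- new
  }
  out <- array(0L, dim(mask))
  out[mask] <- match(lab[mask], sort(unique(lab[mask])))
  out
}

# Erode a logical mask by `r` voxels (box structuring element, so Chebyshev
# radius r); voxels outside the array count as background.
erode_mask <- function(mask, r = 1) {
  offs <- neighbour_offsets(26)
  m <- mask
  for (i in seq_len(r)) {
    acc <- m
    for (s in seq_len(nrow(offs))) {
      acc <- acc & shift3(m, offs[s, ], fill = FALSE)
    }
    m <- acc
  }
  m
}

# Dilate a logical mask by `r` voxels (box structuring element).
dilate_mask <- function(mask, r = 1) {
  offs <- neighbour_offsets(26)
  m <- mask
  for (i in seq_len(r)) {
    acc <- m
    for (s in seq_len(nrow(offs))) {
      acc <- acc | shift3(m, offs[s, ], fill = FALSE)
    }
    m <- acc
  }
  m
}

# Sample skewness (population formula); 0 for degenerate input.
skewness <- function(x) {
  x <- x[is.finite(x)]
  s <- stats::sd(x)
  if (length(x) < 3 || !is.finite(s) || s == 0) return(0)
  mean((x - mean(x))^3) / s^3
}

# Fraction of periodogram power above `cutoff_hz`, frequency 0 excluded.
high_freq_power_fraction <- function(x, tr_seconds, cutoff_hz = 0.1) {
  n <- length(x)
  p <- Mod(stats::fft(x - mean(x)))^2
  nf <- floor(n / 2)
  freqs <- (1:nf) / (n * tr_seconds)
  p <- p[2:(nf + 1)]
  tot <- sum(p)
  if (tot == 0) return(0)
  sum(p[freqs > cutoff_hz]) / tot
}

`%||%` <- function(a, b) if (is.null(a)) b else a
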