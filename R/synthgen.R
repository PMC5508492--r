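# Synthetic multi-subject rs-fMRI generator. Every downstream stage
# (ICA, classification, cleanup, dual regression, metrics) is exercised on
# cohorts produced here, where the latent signal networks and noise sources
# are known exactly.

#' Configuration of the synthetic cohort generator
#'
#' Defaults emulate a typical acute-stroke resting-state acquisition:
#' 3 x 3 x 3 mm voxels, TR 3.0 s, 120 frames, 20 subjects. Signal networks
#' are smooth gray-matter blobs driven by band-limited (0.01-0.1 Hz) time
#' courses; noise components come in three families with distinct spatial and
#' temporal signatures: motion (brain-edge rim, spiky/saw-tooth time
#' courses), physiological (CSF/venous-sinus, narrow-band high-frequency
#' cardio-respiratory surrogate), and vascular (perivascular, slow
#' vascular-tone drift).
#'
#' @param n_subjects Number of subjects in a cohort.
#' @param dim Grid dimensions `(nx, ny, nz)` in voxels.
#' @param voxel_size_mm Voxel edge lengths in mm.
#' @param tr_seconds Repetition time in seconds.
#' @param n_frames Number of volumes T.
#' @param k_signal Number of signal networks.
#' @param k_noise Named integer vector: components per noise family
#'   (`motion`, `physiological`, `vascular`).
#' @param signal_band Passband (Hz) of the signal time courses.
#' @param physio_band Passband (Hz) of physiological noise (must stay below
#'   the Nyquist frequency `1 / (2 TR)`).
#' @param vascular_band Passband (Hz) of vascular-tone noise.
#' @param spike_rate Expected motion spikes per frame (Poisson).
#' @param sawtooth_prob Probability that a motion time course contains a
#'   saw-tooth segment.
#' @param amplitude Named amplitudes (arbitrary BOLD units, applied to
#'   unit-SD time courses) for `signal`, `motion`, `physiological`,
#'   `vascular`. The study data carry no published SNR figures, so these are
#'   free parameters with documented defaults.
#' @param mixing_noise_sd SD of additive white measurement noise.
#' @param offset Constant baseline added inside the brain mask.
#' @param spatial_jitter_sd SD (voxels) of the per-subject jitter applied to
#'   the shared group-level network centres.
#' @param lesion_radius Range (voxels) of the ischemic-lesion radius.
#' @param seed Master seed for the cohort.
#' @return A validated list of class `synth_config`.
#' @export
synth_config <- function(n_subjects = 20,
                         dim = c(32, 32, 24),
                         voxel_size_mm = c(3, 3, 3),
                         tr_seconds = 3,
                         n_frames = 120,
                         k_signal = 5,
                         k_noise = c(motion = 3, physiological = 3, vascular = 2),
                         signal_band = c(0.01, 0.1),
                         physio_band = c(0.12, 0.16),
                         vascular_band = c(0.01, 0.05),
                         spike_rate = 0.05,
                         sawtooth_prob = 0.5,
                         amplitude = c(signal = 1, motion = 3,
                                       physiological = 2, vascular = 1.5),
                         mixing_noise_sd = 0.2,
                         offset = 100,
                         spatial_jitter_sd = 1,
                         lesion_radius = c(2, 4),
                         seed = 1L) {
  cfg <- structure(
    list(n_subjects = as.integer(n_subjects), dim = as.integer(dim),
         voxel_size_mm = as.numeric(voxel_size_mm),
         tr_seconds = as.numeric(tr_seconds), n_frames = as.integer(n_frames),
         k_signal = as.integer(k_signal),
         k_noise = c(motion = as.integer(k_noise[["motion"]] %||% 0),
                     physiological = as.integer(k_noise[["physiological"]] %||% 0),
                     vascular = as.integer(k_noise[["vascular"]] %||% 0)),
         signal_band = as.numeric(signal_band),
         physio_band = as.numeric(physio_band),
         vascular_band = as.numeric(vascular_band),
         spike_rate = as.numeric(spike_rate),
         sawtooth_prob = as.numeric(sawtooth_prob),
         amplitude = amplitude, mixing_noise_sd = as.numeric(mixing_noise_sd),
         offset = as.numeric(offset),
         spatial_jitter_sd = as.numeric(spatial_jitter_sd),
         lesion_radius = as.numeric(lesion_radius), seed = as.integer(seed)),
    class = "synth_config")
  validate_synth_config(cfg)
  cfg
}

validate_synth_config <- function(cfg) {
  bad <- function(field, why) {
    stop(sprintf("invalid synth_config: field `%s` %s", field, why),
         call. = FALSE)
  }
  if (cfg$n_subjects < 1) bad("n_subjects", "must be >= 1")
  if (length(cfg$dim) != 3 || any(cfg$dim < 8)) bad("dim", "must be 3 values >= 8")
  if (any(cfg$voxel_size_mm <= 0)) bad("voxel_size_mm", "must be positive")
  if (cfg$tr_seconds <= 0) bad("tr_seconds", "must be positive")
  if (cfg$n_frames < 2) bad("n_frames", "must be >= 2")
  if (cfg$k_signal < 0) bad("k_signal", "must be >= 0")
  if (any(cfg$k_noise < 0)) bad("k_noise", "must be >= 0")
  if (cfg$k_signal + sum(cfg$k_noise) > cfg$n_frames - 1) {
    bad("k_signal", "+ k_noise must be <= n_frames - 1")
  }
  nyq <- 1 / (2 * cfg$tr_seconds)
  for (f in c("signal_band", "physio_band", "vascular_band")) {
    b <- cfg[[f]]
    if (length(b) != 2 || b[1] <= 0 || b[1] >= b[2] || b[2] > nyq) {
      bad(f, sprintf("must satisfy 0 < low < high <= Nyquist (%.4f Hz)", nyq))
    }
  }
  if (cfg$spike_rate < 0) bad("spike_rate", "must be >= 0")
  if (cfg$mixing_noise_sd < 0) bad("mixing_noise_sd", "must be >= 0")
  if (cfg$spatial_jitter_sd < 0) bad("spatial_jitter_sd", "must be >= 0")
  if (length(cfg$lesion_radius) != 2 || any(cfg$lesion_radius < 0) ||
      cfg$lesion_radius[1] > cfg$lesion_radius[2]) {
    bad("lesion_radius", "must be an increasing non-negative range")
  }
  invisible(cfg)
}

# ---- geometry -------------------------------------------------------------

# Voxel-centre coordinate arrays for a grid.
coord_arrays <- function(dm) {
  list(x = array(rep(seq_len(dm[1]), times = dm[2] * dm[3]), dm),
       y = array(rep(rep(seq_len(dm[2]), each = dm[1]), times = dm[3]), dm),
       z = array(rep(seq_len(dm[3]), each = dm[1] * dm[2]), dm))
}

# Normalised ellipsoidal radius (1 at the brain surface).
ellipsoid_radius <- function(dm) {
  cc <- (dm + 1) / 2
  semi <- pmax(dm * 0.42, 3)
  co <- coord_arrays(dm)
  sqrt(((co$x - cc[1]) / semi[1])^2 + ((co$y - cc[2]) / semi[2])^2 +
         ((co$z - cc[3]) / semi[3])^2)
}

#' Deterministic tissue and lesion geometry for a synthetic brain
#'
#' The brain is an ellipsoid. CSF sits in two central "ventricles", white
#' matter fills the deep interior, gray matter forms a shell; the probability
#' maps sum to at most 1 everywhere. The edge rim is the brain minus its
#' 2-voxel erosion (about 6 mm at 3 mm voxels), and a thin posterior midline
#' surface band stands in for the venous sinuses.
#'
#' @param config A [synth_config()].
#' @return A list of class `tissue_masks`: probability grids `gray`, `white`,
#'   `csf`, logical `edge_rim`, `vessel`, `brain_mask`.
#' @export
make_tissue_masks <- function(config) {
  dm <- config$dim
  rr <- ellipsoid_radius(dm)
  brain <- rr <= 1
  cc <- (dm + 1) / 2
  co <- coord_arrays(dm)
  vent <- function(dy) {
    d2 <- (co$x - cc[1])^2 + (co$y - (cc[2] + dy))^2 + (co$z - (cc[3] + 1))^2
    0.95 * exp(-d2 / (2 * 1.8^2))
  }
  csf <- pmax(vent(-3), vent(3))
  white <- (1 - csf) * stats::plogis((0.55 - rr) / 0.05)
  gray <- exp(-((rr - 0.68) / 0.13)^2)
  tot <- pmax(1, csf + white + gray)
  csf <- csf / tot; white <- white / tot; gray <- gray / tot
  csf[!brain] <- 0; white[!brain] <- 0; gray[!brain] <- 0
  vessel <- brain & abs(co$x - cc[1]) <= 1 &
    (co$y - cc[2]) > 0.3 * pmax(dm[2] * 0.42, 3) & rr > 0.75
  edge_rim <- brain & !erode_mask(brain, 2)
  structure(list(gray = gray, white = white, csf = csf,
                 edge_rim = edge_rim, vessel = vessel, brain_mask = brain),
            class = "tissue_masks")
}

# ---- temporal sources -----------------------------------------------------

# Zero-mean, unit-SD band-limited Gaussian series built from random Fourier
# coefficients restricted to [band[1], band[2]] Hz.
bandlimited_timecourse <- function(n, tr_seconds, band) {
  freqs <- (0:(n - 1)) / (n * tr_seconds)
  half <- 2:(floor(n / 2) + 1) # positive-frequency bins
  keep <- half[freqs[half] >= band[1] & freqs[half] <= band[2]]
  if (length(keep) == 0) {
    stop(sprintf("band [%g, %g] Hz contains no resolvable frequency at T=%d, TR=%g",
                 band[1], band[2], n, tr_seconds))
  }
  spec <- complex(real = rep(0, n), imaginary = rep(0, n))
  spec[keep] <- complex(real = stats::rnorm(length(keep)),
                        imaginary = stats::rnorm(length(keep)))
  conj_idx <- n + 2 - keep
  spec[conj_idx] <- Conj(spec[keep])
  x <- Re(stats::fft(spec, inverse = TRUE)) / n
  x <- x - mean(x)
  s <- stats::sd(x)
  if (s == 0) x else x / s
}

# Motion surrogate: white Gaussian plus Poisson-placed spikes and an optional
# saw-tooth segment; zero mean, unit SD.
motion_timecourse <- function(n, spike_rate, sawtooth_prob) {
  x <- stats::rnorm(n)
  n_spikes <- stats::rpois(1, spike_rate * n)
  if (n_spikes > 0) {
    at <- sample.int(n, min(n_spikes, n))
    x[at] <- x[at] + sample(c(-1, 1), length(at), replace = TRUE) *
      stats::runif(length(at), 6, 10)
  }
  if (stats::runif(1) < sawtooth_prob) {
    len <- max(10L, floor(n / 4))
    start <- sample.int(n - len + 1L, 1)
    period <- 10
    ramp <- 2 * ((seq_len(len) %% period) / period - 0.5)
    x[start:(start + len - 1L)] <- x[start:(start + len - 1L)] + 3 * ramp
  }
  x <- x - mean(x)
  x / stats::sd(x)
}

# ---- spatial sources ------------------------------------------------------

gaussian_blob <- function(dm, center, sd_vox) {
  co <- coord_arrays(dm)
  d2 <- (co$x - center[1])^2 + (co$y - center[2])^2 + (co$z - center[3])^2
  exp(-d2 / (2 * sd_vox^2))
}

# Smooth random field: white noise convolved with an isotropic Gaussian.
smooth_random_field <- function(dm, sigma_vox = 1.5) {
  f <- array(stats::rnorm(prod(dm)), dm)
  r <- ceiling(3 * sigma_vox)
  k <- stats::dnorm(-r:r, sd = sigma_vox)
  k <- k / sum(k)
  for (axis in 1:3) {
    acc <- array(0, dm)
    for (i in seq_along(k)) {
      d <- c(0L, 0L, 0L)
      d[axis] <- i - r - 1L
      acc <- acc + k[i] * shift3(f, d, fill = 0)
    }
    f <- acc
  }
  f
}

normalise_map <- function(m) {
  mx <- max(abs(m))
  if (mx == 0) m else m / mx
}

# Scale a source map to unit RMS over the brain, so squared amplitudes are
# per-component variance contributions averaged over brain voxels.
rms_normalise_map <- function(m, brain) {
  r <- sqrt(mean(m[brain]^2))
  if (r == 0) m else m / r
}

# Sample a voxel index (x, y, z) with probability proportional to `weights`.
sample_center <- function(weights) {
  idx <- sample.int(length(weights), 1, prob = pmax(as.vector(weights), 0))
  arrayInd(idx, dim(weights))[1, ]
}

# Group-level network centres shared by a cohort.
group_signal_centers <- function(config, masks) {
  if (config$k_signal == 0) return(matrix(numeric(0), 0, 3))
  t(vapply(seq_len(config$k_signal), function(k) sample_center(masks$gray),
           numeric(3)))
}

#' Generate one ischemic lesion mask
#'
#' A single connected spherical blob inside the brain, with radius drawn from
#' the configured range; at least one voxel is always produced.
#'
#' @param config A [synth_config()].
#' @param seed Integer seed.
#' @return 3D logical array on the configured grid.
#' @export
make_lesion_mask <- function(config, seed, masks = NULL) {
  if (is.null(masks)) masks <- make_tissue_masks(config)
  withr::with_seed(seed, {
    deep <- erode_mask(masks$brain_mask, 3)
    if (!any(deep)) deep <- masks$brain_mask
    center <- sample_center(deep * 1)
    radius <- stats::runif(1, config$lesion_radius[1], config$lesion_radius[2])
    co <- coord_arrays(config$dim)
    d2 <- (co$x - center[1])^2 + (co$y - center[2])^2 + (co$z - center[3])^2
    lesion <- d2 <= radius^2 & masks$brain_mask
    if (!any(lesion)) {
      lesion[center[1], center[2], center[3]] <- TRUE
    }
    lesion
  })
}

# ---- subject / cohort -----------------------------------------------------

#' Generate one synthetic subject
#'
#' The voxel data are an exact linear mixing of the ground-truth sources,
#' `offset + sum_k map_k (x) tc_k + white noise`, inside the brain mask and
#' zero outside. Identical `(config, subject_seed)` reproduce bit-identical
#' output.
#'
#' @param config A [synth_config()].
#' @param subject_seed Integer seed for this subject.
#' @param group_centers Optional `k_signal x 3` matrix of shared group-level
#'   network centres (as produced inside [make_cohort()]); when `NULL` the
#'   subject draws its own.
#' @return A list of class `synth_subject`: `image` ([image4d()]),
#'   `masks` ([make_tissue_masks()] output) and `truth` (class
#'   `ground_truth`: 4D `signal_maps` / `noise_maps`, zero-mean scaled
#'   time courses, noise `subtype` tags, `mixing_noise_sd`, `lesion_mask`).
#' @export
make_subject <- function(config, subject_seed, group_centers = NULL,
                         masks = NULL) {
  validate_synth_config(config)
  if (is.null(masks)) masks <- make_tissue_masks(config)
  dm <- config$dim
  n <- config$n_frames
  V <- sum(masks$brain_mask)
  lesion <- make_lesion_mask(config, derive_seed(subject_seed, "lesion"),
                             masks = masks)

  withr::with_seed(subject_seed, {
    if (is.null(group_centers)) group_centers <- group_signal_centers(config, masks)
    ks <- config$k_signal
    sig_maps <- array(0, c(dm, max(ks, 1)))[, , , seq_len(ks), drop = FALSE]
    sig_tc <- matrix(0, n, ks)
    for (k in seq_len(ks)) {
      jitter <- stats::rnorm(3, 0, config$spatial_jitter_sd)
      m <- gaussian_blob(dm, group_centers[k, ] + jitter, 2.5) * masks$gray
      sig_maps[, , , k] <- rms_normalise_map(m, masks$brain_mask)
      sig_tc[, k] <- bandlimited_timecourse(n, config$tr_seconds,
                                            config$signal_band) *
        config$amplitude[["signal"]]
    }

    kn <- config$k_noise
    kt <- sum(kn)
    subtype <- rep(names(kn), times = kn)
    noise_maps <- array(0, c(dm, max(kt, 1)))[, , , seq_len(kt), drop = FALSE]
    noise_tc <- matrix(0, n, kt)
    for (j in seq_len(kt)) {
      fld <- abs(smooth_random_field(dm, 1.5))
      if (subtype[j] == "motion") {
        m <- masks$edge_rim * fld
        tc <- motion_timecourse(n, config$spike_rate, config$sawtooth_prob)
        amp <- config$amplitude[["motion"]]
      } else if (subtype[j] == "physiological") {
        m <- (masks$csf + masks$vessel) * fld
        tc <- bandlimited_timecourse(n, config$tr_seconds, config$physio_band)
        amp <- config$amplitude[["physiological"]]
      } else {
        m <- (dilate_mask(masks$vessel, 1) + 0.5 * masks$csf) * fld
        tc <- bandlimited_timecourse(n, config$tr_seconds, config$vascular_band)
        amp <- config$amplitude[["vascular"]]
      }
      noise_maps[, , , j] <- rms_normalise_map(m, masks$brain_mask)
      noise_tc[, j] <- tc * amp
    }

    flat <- matrix(0, prod(dm), n)
    inmask <- as.vector(masks$brain_mask)
    acc <- matrix(config$offset, V, n)
    if (ks + kt > 0) {
      map_mat <- matrix(0, V, ks + kt)
      for (k in seq_len(ks)) map_mat[, k] <- sig_maps[, , , k][masks$brain_mask]
      for (j in seq_len(kt)) {
        map_mat[, ks + j] <- noise_maps[, , , j][masks$brain_mask]
      }
      acc <- acc + map_mat %*% t(cbind(sig_tc, noise_tc))
    }
    if (config$mixing_noise_sd > 0) {
      acc <- acc + matrix(stats::rnorm(V * n, 0, config$mixing_noise_sd), V, n)
    }
    flat[inmask, ] <- acc
    img <- image4d(array(flat, c(dm, n)),
                   voxel_size_mm = config$voxel_size_mm,
                   tr_seconds = config$tr_seconds,
                   brain_mask = masks$brain_mask)

    truth <- structure(
      list(signal_maps = sig_maps, signal_timecourses = sig_tc,
           noise_maps = noise_maps, noise_timecourses = noise_tc,
           subtype = subtype, mixing_noise_sd = config$mixing_noise_sd,
           lesion_mask = lesion, offset = config$offset),
      class = "ground_truth")
    structure(list(image = img, masks = masks, truth = truth),
              class = "synth_subject")
  })
}

#' Generate a synthetic cohort
#'
#' Subjects share group-level network centres (with per-subject Gaussian
#' spatial jitter) and have independent time courses and noise; per-subject
#' seeds are derived deterministically from the master seed in `config`.
#'
#' @param config A [synth_config()] with `n_subjects >= 2`.
#' @return A list of class `synth_cohort` of `n_subjects`
#'   [make_subject()] results, with the config attached as an attribute.
#' @export
make_cohort <- function(config) {
  validate_synth_config(config)
  if (config$n_subjects < 2) {
    stop("a cohort needs n_subjects >= 2 (group metrics are undefined otherwise)")
  }
  masks <- make_tissue_masks(config)
  centers <- withr::with_seed(derive_seed(config$seed, "group"),
                              group_signal_centers(config, masks))
  subjects <- lapply(seq_len(config$n_subjects), function(i) {
    make_subject(config, derive_seed(config$seed, "subject", i),
                 group_centers = centers, masks = masks)
  })
  structure(subjects, class = "synth_cohort", config = config,
            group_centers = centers)
}

#' Build a network-of-interest atlas from a cohort's ground truth
#'
#' The first `k_signal` templates are the voxelwise-standardised group-mean
#' signal maps; the remaining templates are distractor maps constructed to be
#' spatially uncorrelated (|r| < 0.2 in-brain) with every signal map, so
#' dual-regression specificity can be probed.
#'
#' @param cohort A [make_cohort()] result.
#' @param n_templates Total number of templates (>= `k_signal`).
#' @param seed Seed for the distractor construction.
#' @return A list of class `noi_atlas`: 4D `templates` (one Z-valued map per
#'   volume), `labels`, `gray_matter`, `brain_mask`, `voxel_size_mm`.
#' @export
make_noi_atlas <- function(cohort, n_templates, seed = 1L) {
  config <- attr(cohort, "config")
  ks <- config$k_signal
  if (n_templates < ks) stop("n_templates must be >= k_signal")
  masks <- cohort[[1]]$masks
  brain <- masks$brain_mask
  dm <- config$dim
  zscore_map <- function(m) {
    v <- m[brain]
    s <- stats::sd(v)
    out <- array(0, dm)
    out[brain] <- if (s == 0) 0 else (v - mean(v)) / s
    out
  }
  templates <- array(0, c(dm, n_templates))
  sig_flat <- matrix(0, sum(brain), max(ks, 1))[, seq_len(ks), drop = FALSE]
  for (k in seq_len(ks)) {
    gm <- Reduce(`+`, lapply(cohort, function(s) s$truth$signal_maps[, , , k])) /
      length(cohort)
    templates[, , , k] <- zscore_map(gm)
    sig_flat[, k] <- templates[, , , k][brain]
  }
  withr::with_seed(derive_seed(seed, "atlas"), {
    for (j in seq_len(n_templates - ks)) {
      for (try in 1:200) {
        # distractors live anywhere in the brain: their contract is
        # decorrelation from the signal networks, not tissue specificity
        m <- zscore_map(gaussian_blob(dm, sample_center(masks$brain_mask * 1),
                                      2.5))
        ok <- ks == 0 ||
          all(abs(stats::cor(m[brain], sig_flat)) < 0.2)
        # keep earlier distractors at arm's length too, so the atlas design
        # stays well conditioned
        if (ok && j > 1) {
          prev <- vapply(seq_len(j - 1),
                         function(p) templates[, , , ks + p][brain],
                         numeric(sum(brain)))
          ok <- all(abs(stats::cor(m[brain], prev)) < 0.5)
        }
        if (ok) break
      }
      if (!ok) stop("could not construct a decorrelated distractor template")
      templates[, , , ks + j] <- m
    }
  })
  labels <- c(sprintf("network_%02d", seq_len(ks)),
              if (n_templates > ks) sprintf("distractor_%02d",
                                            seq_len(n_templates - ks)))
  structure(list(templates = templates, labels = labels,
                 gray_matter = masks$gray, brain_mask = brain,
                 voxel_size_mm = config$voxel_size_mm),
            class = "noi_atlas")
}

#' Reconstruct the noiseless mixing from a subject's ground truth
#'
#' With `mixing_noise_sd = 0` this equals the generated voxel data to machine
#' precision (energy accounting of the generator).
#'
#' @param subject A [make_subject()] result.
#' @return 4D array on the subject's grid.
#' @export
reconstruct_from_truth <- function(subject) {
  tr <- subject$truth
  img <- subject$image
  dm <- dim(img$voxels)[1:3]
  n <- n_frames(img)
  V <- sum(img$brain_mask)
  acc <- matrix(tr$offset, V, n)
  for (k in seq_len(ncol(tr$signal_timecourses))) {
    acc <- acc + tr$signal_maps[, , , k][img$brain_mask] %o%
      tr$signal_timecourses[, k]
  }
  for (j in seq_len(ncol(tr$noise_timecourses))) {
    acc <- acc + tr$noise_maps[, , , j][img$brain_mask] %o%
      tr$noise_timecourses[, j]
  }
  flat <- matrix(0, prod(dm), n)
  flat[as.vector(img$brain_mask), ] <- acc
  array(flat, c(dm, n))
}

#' Write a subject's image, masks and ground truth to disk
#'
#' NIfTI for the 4D data, 3D masks and source maps; TSV for time courses; a
#' JSON sidecar for scalar ground-truth metadata.
#'
#' @param subject A [make_subject()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_subject <- function(subject, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_image4d(subject$image, file.path(dir, "bold.nii.gz"))
  write_mask_nifti <- function(arr, name) {
    nii <- RNifti::asNifti(array(as.numeric(arr), dim(arr)))
    RNifti::pixdim(nii) <- subject$image$voxel_size_mm
    RNifti::writeNifti(nii, file.path(dir, name))
  }
  write_mask_nifti(subject$masks$gray, "gray.nii.gz")
  write_mask_nifti(subject$masks$white, "white.nii.gz")
  write_mask_nifti(subject$masks$csf, "csf.nii.gz")
  write_mask_nifti(subject$masks$edge_rim, "edge_rim.nii.gz")
  write_mask_nifti(subject$masks$vessel, "vessel.nii.gz")
  write_mask_nifti(subject$truth$lesion_mask, "lesion.nii.gz")
  tr <- subject$truth
  if (length(tr$signal_maps) > 0) {
    nii <- RNifti::asNifti(tr$signal_maps)
    RNifti::writeNifti(nii, file.path(dir, "signal_maps.nii.gz"))
  }
  if (length(tr$noise_maps) > 0) {
    nii <- RNifti::asNifti(tr$noise_maps)
    RNifti::writeNifti(nii, file.path(dir, "noise_maps.nii.gz"))
  }
  utils::write.table(tr$signal_timecourses,
                     file.path(dir, "signal_timecourses.tsv"),
                     sep = "\t", row.names = FALSE, col.names = TRUE)
  utils::write.table(tr$noise_timecourses,
                     file.path(dir, "noise_timecourses.tsv"),
                     sep = "\t", row.names = FALSE, col.names = TRUE)
  jsonlite::write_json(
    list(subtype = tr$subtype, mixing_noise_sd = tr$mixing_noise_sd,
         offset = tr$offset,
         tr_seconds = subject$image$tr_seconds,
         voxel_size_mm = subject$image$voxel_size_mm),
    file.path(dir, "ground_truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
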