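# Shared fixtures and a cache for the expensive cohort-level simulations so
# several test files can reuse one computation.

the_cache <- new.env(parent = emptyenv())

cache_get <- function(key, fn) {
  if (!exists(key, envir = the_cache)) assign(key, fn(), envir = the_cache)
  get(key, envir = the_cache)
}

# A small, fast cohort configuration for unit tests.
small_config <- function(...) {
  args <- list(n_subjects = 4, dim = c(20, 20, 16), seed = 5)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(synth_config, args)
}

# Noise-free image built from sparse disjoint spatial sources with orthogonal
# time courses: the canonical exactly-recoverable ICA fixture.
disjoint_source_image <- function(n_sources = 3, dm = c(12, 12, 8), Tn = 40,
                                  seed = 1) {
  withr::with_seed(seed, {
    V <- prod(dm)
    S <- matrix(0, n_sources, V)
    starts <- seq(1, V - 80, length.out = n_sources)
    for (k in seq_len(n_sources)) {
      idx <- floor(starts[k]) + 0:59
      S[k, idx] <- stats::rexp(length(idx))
    }
    A <- qr.Q(qr(matrix(stats::rnorm(Tn * n_sources), Tn, n_sources)))
    X <- A %*% S
    img <- image4d(aperm(array(X, c(Tn, dm)), c(2, 3, 4, 1)),
                   brain_mask = array(TRUE, dm))
    list(img = img, S = S, A = A)
  })
}

# White-noise image on an all-true mask.
white_noise_image <- function(dm = c(10, 10, 8), Tn = 30, sd = 1, seed = 1,
                              tr_seconds = 3) {
  withr::with_seed(seed, {
    image4d(array(stats::rnorm(prod(dm) * Tn, sd = sd), c(dm, Tn)),
            tr_seconds = tr_seconds, brain_mask = array(TRUE, dm))
  })
}

# Minimal connectivity_result stub for reproducibility tests.
fake_connectivity <- function(betas, mask, labels = NULL) {
  structure(list(timecourses = NULL, zmaps = betas, betas = betas,
                 labels = labels, mask = mask, subject = NA),
            class = "connectivity_result")
}

# Per-seed study summary on the default 20-subject cohort: components are
# wrapped from ground truth, cleanup uses ground-truth labels, and all
# cohort-level metrics are reduced to scalars.
run_seed_study <- function(seed) {
  cfg <- synth_config(seed = seed)
  cohort <- make_cohort(cfg)
  masks <- cohort[[1]]$masks
  atlas <- make_noi_atlas(cohort, 20, seed = seed)
  wraps <- lapply(cohort, wrap_ground_truth)
  feats <- lapply(wraps, component_features, masks = masks)
  labs <- lapply(wraps, function(d) attr(d, "labels"))

  sweep_all <- loso_sweep(feats, labs, mode = "all-noise")
  sel_all <- select_optimal_threshold(sweep_all)
  labs_mot <- lapply(labs, labels_for_mode, mode = "motion-only")
  scorer_all <- train_scorer(feats, labs, mode = "all-noise")
  scorer_mot <- train_scorer(feats, labs_mot, mode = "motion-only")

  n_sig <- cfg$k_signal
  matched <- seq_len(n_sig)
  rim <- masks$edge_rim
  deep_gray <- masks$gray > 0.5 & !masks$edge_rim

  dro <- vector("list", length(cohort))
  drc <- vector("list", length(cohort))
  ident_orig <- ident_clean <- numeric(length(cohort))
  cor_orig <- cor_clean <- numeric(length(cohort))
  rim_dstd <- deep_dstd <- numeric(length(cohort))
  n_removed_all_scored <- n_removed_mot_scored <- integer(length(cohort))

  thr_all <- if (is.na(sel_all)) 50 else sel_all
  sweep_mot <- loso_sweep(feats, labs_mot, mode = "motion-only")
  sel_mot <- select_optimal_threshold(sweep_mot)
  thr_mot <- if (is.na(sel_mot)) 50 else sel_mot

  for (i in seq_along(cohort)) {
    s <- cohort[[i]]
    pre <- highpass_filter(gaussian_smooth(s$image, 5), 100)
    lab <- labs[[i]]
    all_ids <- lab$component[lab$label == "noise"]
    mot_ids <- lab$component[!is.na(lab$subtype) & lab$subtype == "motion"]
    cl_all <- nonaggressive_clean(pre, wraps[[i]], all_ids)
    cl_mot <- nonaggressive_clean(pre, wraps[[i]], mot_ids)

    dro[[i]] <- template_dual_regression(pre, atlas, i)
    drc[[i]] <- template_dual_regression(cl_all$cleaned, atlas, i)

    tvec <- function(k) atlas$templates[, , , k][atlas$brain_mask]
    ident_orig[i] <- mean(vapply(matched, function(k)
      rsn_identifiability(dro[[i]]$zmaps[k, ], tvec(k), 2.3), numeric(1)))
    ident_clean[i] <- mean(vapply(matched, function(k)
      rsn_identifiability(drc[[i]]$zmaps[k, ], tvec(k), 2.3), numeric(1)))

    cor_orig[i] <- mean(vapply(matched, function(k)
      abs(stats::cor(dro[[i]]$timecourses[, k],
                     s$truth$signal_timecourses[, k])), numeric(1)))
    cor_clean[i] <- mean(vapply(matched, function(k)
      abs(stats::cor(drc[[i]]$timecourses[, k],
                     s$truth$signal_timecourses[, k])), numeric(1)))

    dm_mot <- delta_std_map(pre, cl_mot$cleaned)
    rim_dstd[i] <- mean(dm_mot[rim], na.rm = TRUE)
    deep_dstd[i] <- mean(dm_mot[deep_gray], na.rm = TRUE)

    sc_all <- predict_scores(scorer_all, feats[[i]])$score
    sc_mot <- predict_scores(scorer_mot, feats[[i]])$score
    n_removed_all_scored[i] <- sum(sc_all >= thr_all)
    n_removed_mot_scored[i] <- sum(sc_mot >= thr_mot)
  }

  repro_orig <- split_half_reproducibility(dro, atlas$gray_matter,
                                           n_splits = 100, seed = seed)
  repro_clean <- split_half_reproducibility(drc, atlas$gray_matter,
                                            n_splits = 100, seed = seed)

  list(
    selected_threshold = sel_all,
    selected_threshold_motion = sel_mot,
    mean_ident_orig = mean(ident_orig),
    mean_ident_clean = mean(ident_clean),
    pseudo_z_orig = mean(repro_orig$mean_pseudo_z[matched]),
    pseudo_z_clean = mean(repro_clean$mean_pseudo_z[matched]),
    cor_orig = mean(cor_orig),
    cor_clean = mean(cor_clean),
    rim_dstd = mean(rim_dstd),
    deep_dstd = mean(deep_dstd),
    n_removed_all = n_removed_all_scored,
    n_removed_mot = n_removed_mot_scored)
}

study_runs <- function() {
  cache_get("study_runs", function() {
    lapply(101:110, run_seed_study)
  })
}
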