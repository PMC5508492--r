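# Helper: decomposition with hand-built maps/time courses on the small grid.
handmade_decomp <- function(maps, tcs, masks) {
  V <- sum(masks$brain_mask)
  component_decomposition(
    spatial_maps = maps, timecourses = tcs,
    variance_fraction = rep(0, nrow(maps)), mask = masks$brain_mask,
    mean_volume = rep(0, V), tr_seconds = 3)
}

test_that("spatial features read edge, speckle and CSF concentration correctly", {
  masks <- make_tissue_masks(small_config())
  brain <- masks$brain_mask
  V <- sum(brain)
  rim_in <- masks$edge_rim[brain]
  csf_in <- (masks$csf > 0.5 | masks$vessel)[brain]
  Tn <- 120
  maps <- rbind(
    ifelse(rim_in, 5, 0),        # entirely suprathreshold inside the rim
    ifelse(csf_in, 5, 0),        # entirely in CSF/vessel
    rep(0, V))                   # nothing suprathreshold
  tcs <- matrix(stats::rnorm(Tn * 3), Tn)
  f <- component_features(handmade_decomp(maps, tcs, masks), masks)
  expect_equal(f$edge_fraction[1], 1)
  expect_equal(f$csf_vessel_fraction[2], 1)
  expect_equal(f$speckle_extent[1], sum(rim_in) / V)
  expect_equal(f$speckle_extent[3], 0)
  expect_equal(f$n_clusters[3], 0L)
  expect_gte(f$n_clusters[1], 1L)
})

test_that("temporal features: band-limited sine, impulse spike, saw-tooth", {
  masks <- make_tissue_masks(small_config())
  V <- sum(masks$brain_mask)
  Tn <- 120
  t <- seq_len(Tn)
  sine <- sin(2 * pi * 0.05 * t * 3)        # 0.05 Hz at TR = 3
  fast <- sin(2 * pi * 0.15 * t * 3)        # above the 0.1 Hz boundary
  impulse <- c(rep(0, 60), 1, rep(0, Tn - 61))
  saw <- rep(2 * ((t[1:20] %% 10) / 10 - 0.5), 6)
  maps <- matrix(stats::rnorm(4 * V), 4)
  tcs <- cbind(sine, fast, impulse, saw)
  f <- component_features(handmade_decomp(maps, tcs, masks), masks)
  expect_lt(f$high_freq_fraction[1], 0.05)
  expect_gt(f$high_freq_fraction[2], 0.9)
  expect_gt(f$spike_score[3], 10)
  expect_gt(f$sawtooth_score[4], f$sawtooth_score[1])
  # constant time course has spike score 0
  tcs0 <- cbind(rep(1, Tn), sine, fast, impulse)
  f0 <- component_features(handmade_decomp(maps, tcs0, masks), masks)
  expect_equal(f0$spike_score[1], 0)
  expect_equal(f0$high_freq_fraction[1], 0)
})

test_that("fixed noise scores separate feature extremes and modes differ as designed", {
  signal_like <- tibble::tibble(
    component = 1L, edge_fraction = 0, speckle_extent = 0, n_clusters = 1L,
    high_freq_fraction = 0, spike_score = 0, sawtooth_score = 0,
    csf_vessel_fraction = 0)
  noise_like <- tibble::tibble(
    component = 1L, edge_fraction = 1, speckle_extent = 0.5, n_clusters = 15L,
    high_freq_fraction = 1, spike_score = 20, sawtooth_score = 5,
    csf_vessel_fraction = 1)
  expect_lt(noise_score(signal_like, "all-noise")$score, 20)
  expect_gt(noise_score(noise_like, "all-noise")$score, 80)
  # motion-only mode ignores csf_vessel_fraction
  perturbed <- noise_like
  perturbed$csf_vessel_fraction <- 0
  expect_equal(noise_score(noise_like, "motion-only")$score,
               noise_score(perturbed, "motion-only")$score)
  # component whose noise features are all zero (bar the single cluster)
  expect_lt(noise_score(signal_like, "all-noise")$score, 2)
  expect_equal(noise_score(signal_like, "motion-only")$score, 0)
})

make_separable_cohort <- function(n_subjects = 4, n_comp = 12, seed = 1) {
  withr::with_seed(seed, {
    lapply(seq_len(n_subjects), function(i) {
      noise <- rep(c(FALSE, TRUE), length.out = n_comp)
      f <- tibble::tibble(
        component = seq_len(n_comp),
        edge_fraction = ifelse(noise, stats::runif(n_comp, 0.7, 1),
                               stats::runif(n_comp, 0, 0.2)),
        speckle_extent = stats::runif(n_comp, 0, 0.1),
        n_clusters = sample(1:3, n_comp, TRUE),
        high_freq_fraction = ifelse(noise, stats::runif(n_comp, 0.6, 1),
                                    stats::runif(n_comp, 0, 0.2)),
        spike_score = ifelse(noise, stats::runif(n_comp, 8, 15),
                             stats::runif(n_comp, 0, 3)),
        sawtooth_score = stats::runif(n_comp, 0, 0.5),
        csf_vessel_fraction = stats::runif(n_comp, 0, 0.2))
      l <- tibble::tibble(component = seq_len(n_comp),
                          label = ifelse(noise, "noise", "signal"))
      list(features = f, labels = l)
    })
  })
}

test_that("training on separable data yields a perfect LOSO sweep at mid thresholds", {
  co <- make_separable_cohort()
  feats <- lapply(co, `[[`, "features")
  labs <- lapply(co, `[[`, "labels")
  sw <- loso_sweep(feats, labs, thresholds = c(10, 50, 90))
  mid <- sw[sw$threshold == 50, ]
  expect_equal(mid$mean_tpr, 100)
  expect_equal(mid$mean_tnr, 100)
  # training is deterministic
  s1 <- train_scorer(feats, labs)
  s2 <- train_scorer(feats, labs)
  expect_identical(predict_scores(s1, feats[[1]]),
                   predict_scores(s2, feats[[1]]))
  expect_error(train_scorer(feats, lapply(labs, function(l) {
    l$label <- "noise"; l
  })), "both")
})

test_that("shuffled labels give chance-level LOSO accuracy", {
  co <- make_separable_cohort(n_subjects = 6, n_comp = 30, seed = 2)
  feats <- lapply(co, `[[`, "features")
  labs <- withr::with_seed(3, lapply(co, function(s) {
    l <- s$labels
    l$label <- sample(l$label)
    l
  }))
  acc <- numeric(0)
  for (i in seq_along(feats)) {
    sc <- predict_scores(train_scorer(feats[-i], labs[-i]), feats[[i]])$score
    pred <- ifelse(sc >= 50, "noise", "signal")
    acc <- c(acc, pred == labs[[i]]$label)
  }
  # binomial CI around 0.5 at n = 180
  expect_gt(mean(acc), 0.35)
  expect_lt(mean(acc), 0.65)
})

test_that("TPR/TNR arithmetic, order invariance and error cases", {
  truth <- tibble::tibble(component = 1:20,
                          label = rep(c("signal", "noise"), each = 10))
  pred <- truth
  expect_equal(evaluate_tpr_tnr(pred, truth), c(tpr = 100, tnr = 100))
  # 9/10 signal correct, 8/10 noise correct
  pred2 <- truth
  pred2$label[1] <- "noise"
  pred2$label[11:12] <- "signal"
  expect_equal(evaluate_tpr_tnr(pred2, truth), c(tpr = 90, tnr = 80))
  # invariance to reordering
  shuffle <- withr::with_seed(1, sample(20))
  expect_equal(evaluate_tpr_tnr(pred2[shuffle, ], truth),
               c(tpr = 90, tnr = 80))
  # all predicted noise against 4 signal + 6 noise truth
  truth46 <- tibble::tibble(component = 1:10,
                            label = rep(c("signal", "noise"), c(4, 6)))
  pred46 <- truth46; pred46$label <- "noise"
  expect_equal(evaluate_tpr_tnr(pred46, truth46), c(tpr = 0, tnr = 100))
  expect_error(evaluate_tpr_tnr(pred46, truth46[1:5, ]), "same components")
  one_class <- tibble::tibble(component = 1:4, label = "noise")
  expect_error(evaluate_tpr_tnr(one_class, one_class), "both")
})

test_that("sweep monotonicity: TPR never falls and TNR never rises with threshold", {
  for (rep in 1:10) {
    co <- make_separable_cohort(n_subjects = 3, n_comp = 10, seed = rep)
    feats <- lapply(co, `[[`, "features")
    labs <- withr::with_seed(rep + 100, lapply(co, function(s) {
      l <- s$labels
      if (rep %% 2 == 0) l$label <- sample(l$label) # half the cases shuffled
      l
    }))
    sw <- loso_sweep(feats, labs, thresholds = seq(0, 100, by = 10))
    expect_true(all(diff(sw$mean_tpr) >= -1e-9))
    expect_true(all(diff(sw$mean_tnr) <= 1e-9))
  }
})

test_that("single-class subjects are excluded from LOSO statistics", {
  co <- make_separable_cohort(n_subjects = 3)
  feats <- lapply(co, `[[`, "features")
  labs <- lapply(co, `[[`, "labels")
  labs[[2]]$label <- "noise"
  expect_message(sw <- loso_sweep(feats, labs, thresholds = 50), "excluded")
  expect_equal(attr(sw, "excluded"), 2L)
  expect_false(any(is.na(sw$mean_tpr)))
})

test_that("the optimal-threshold rule handles edge cases", {
  one <- threshold_sweep(25, 100, 100, 50, 50)
  expect_equal(select_optimal_threshold(one), 25)
  # no threshold above the TPR floor
  low <- threshold_sweep(c(1, 2), c(80, 85), c(80, 85), c(50, 60), c(50, 60))
  expect_true(is.na(select_optimal_threshold(low)))
  # TPR fine but TNR maximum below the minimum
  weak <- threshold_sweep(c(1, 2), c(95, 99), c(95, 99), c(4, 8), c(4, 8))
  expect_true(is.na(select_optimal_threshold(weak)))
  # ties go to the largest threshold
  tie <- threshold_sweep(c(5, 10), c(95, 95), c(95, 95), c(40, 40), c(40, 40))
  expect_equal(select_optimal_threshold(tie), 10)
  empty <- threshold_sweep(numeric(0), numeric(0), numeric(0), numeric(0),
                           numeric(0))
  expect_true(is.na(select_optimal_threshold(empty)))
})

test_that("lesion overlap is the in-lesion fraction of component voxels", {
  dm <- c(10, 10, 5)
  comp <- array(FALSE, dm); comp[1:10, 1, 1] <- TRUE
  les <- array(FALSE, dm); les[5:8, 4, 4] <- TRUE
  expect_equal(lesion_overlap(comp, les), 0)
  les2 <- array(TRUE, dm)
  expect_equal(lesion_overlap(comp, les2), 1)
  comp100 <- array(FALSE, dm); comp100[1:100] <- TRUE
  les3 <- array(FALSE, dm); les3[1:2] <- TRUE
  expect_equal(lesion_overlap(comp100, les3), 0.02)
  expect_error(lesion_overlap(array(FALSE, dm), les), "empty")
  expect_error(lesion_overlap(comp, array(FALSE, c(2, 2, 2))), "grid")
})

test_that("motion-only mode relabels non-motion noise as signal", {
  lab <- tibble::tibble(component = 1:4,
                        label = c("signal", "noise", "noise", "noise"),
                        subtype = c(NA, "motion", "physiological", "vascular"))
  out <- labels_for_mode(lab, "motion-only")
  expect_equal(out$label, c("signal", "noise", "signal", "signal"))
  expect_identical(labels_for_mode(lab, "all-noise"), lab)
  # without subtype information labels pass through unchanged
  lab2 <- lab[, c("component", "label")]
  expect_identical(labels_for_mode(lab2, "motion-only"), lab2)
})

test_that("rule-based labelling flags the injected noise families", {
  cfg <- small_config()
  s <- make_subject(cfg, 23)
  d <- wrap_ground_truth(s)
  f <- component_features(d, s$masks)
  r <- rule_label(f)
  truth <- attr(d, "labels")$label
  # the rim-localised motion components must be caught
  motion <- which(attr(d, "labels")$subtype == "motion")
  expect_true(all(r$label[motion] == "noise"))
})

test_that("on default cohorts the trained scorer admits a qualifying threshold", {
  runs <- study_runs()
  admits <- vapply(runs, function(r) !is.na(r$selected_threshold), logical(1))
  expect_gte(sum(admits), 9)
})
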