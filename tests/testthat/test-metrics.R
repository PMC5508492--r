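test_that("identifiability: uniform |Z| gives 1, template-shaped Z exceeds 1", {
  withr::with_seed(1, {
    V <- 500
    tpl <- stats::rnorm(V)
    mask <- rep(TRUE, V)
    expect_equal(rsn_identifiability(rep(2, V), tpl, 1.5), 1)
    # Z equal to the template concentrates |Z| inside its own mask
    expect_gt(rsn_identifiability(tpl, tpl, 1.5), 1)
    # sensitivity thresholds all return finite ratios on the same fixture
    tpl_wide <- tpl * 2
    for (thr in c(1.5, 2.3, 3.1)) {
      expect_true(is.finite(rsn_identifiability(tpl_wide, tpl_wide, thr)))
    }
    expect_error(rsn_identifiability(tpl, tpl * 0, 2.3), "empty")
    expect_error(rsn_identifiability(rep(0, V), tpl, 1.5), "zero mean")
  })
})

test_that("split-half reproducibility: shared maps give large pseudo-Z, noise gives none", {
  dm <- c(10, 10, 6)
  mask <- array(TRUE, dm)
  gm <- array(1, dm)
  N <- 6; V <- prod(dm)
  withr::with_seed(2, {
    shared <- matrix(stats::rnorm(N * V), N) # near-orthogonal random NOIs
    consistent <- lapply(1:8, function(i) {
      fake_connectivity(shared + 0.05 * matrix(stats::rnorm(N * V), N), mask)
    })
    noisy <- lapply(1:10, function(i) {
      fake_connectivity(matrix(stats::rnorm(N * V), N), mask)
    })
  })
  rc <- split_half_reproducibility(consistent, gm, n_splits = 50, seed = 3)
  expect_true(all(rc$mean_pseudo_z > 3))
  # independent noise: no NOI reproduces; the distinct-split budget of a
  # small cohort limits how tightly single-NOI means concentrate
  rn <- split_half_reproducibility(noisy, gm, n_splits = 100, seed = 3)
  expect_lt(abs(mean(rn$mean_pseudo_z)), 0.5)
  expect_lt(max(abs(rn$mean_pseudo_z)), 1.5)
  # identical subjects: the matched correlation is exactly 1 in every split
  dup <- lapply(1:4, function(i) fake_connectivity(shared, mask))
  rd <- split_half_reproducibility(dup, gm, n_splits = 5, seed = 1)
  expect_true(all(rd$mean_pseudo_z > 3))
  expect_error(split_half_reproducibility(noisy[1:3], gm, 10), "at least 4")
  # odd cohorts are trimmed with a message
  expect_message(split_half_reproducibility(consistent[1:5], gm, 5, seed = 1),
                 "even subset")
  # determinism of the split sequence
  r1 <- split_half_reproducibility(noisy, gm, n_splits = 20, seed = 9)
  r2 <- split_half_reproducibility(noisy, gm, n_splits = 20, seed = 9)
  expect_identical(r1$mean_pseudo_z, r2$mean_pseudo_z)
})

test_that("tDoF loss percentages follow the removed / volumes ratio", {
  expect_equal(tdof_loss_percent(0, 120), 0)
  expect_equal(tdof_loss_percent(30, 120), 25)
  expect_equal(tdof_loss_percent(42, 120), 35)
  expect_error(tdof_loss_percent(-1, 120), "0 <=")
  expect_error(tdof_loss_percent(121, 120), "0 <=")
})

test_that("%dSTD maps follow their closed forms", {
  cfg <- synth_config(n_subjects = 2, dim = c(10, 10, 8), n_frames = 30,
                      seed = 3)
  s <- make_subject(cfg, 5)
  img <- s$image
  expect_equal(max(abs(delta_std_map(img, img)[img$brain_mask])), 0)
  # corrected = mean + 0.5 (original - mean) -> 50 everywhere
  X <- as_timeseries_matrix(img)
  mu <- colMeans(X)
  half <- icadenoise:::set_timeseries_matrix(
    img, 0.5 * sweep(X, 2, mu) + rep(1, nrow(X)) %o% mu)
  d50 <- delta_std_map(img, half)
  expect_equal(unique(round(d50[img$brain_mask], 8)), 50)
  # corrected = temporal mean exactly -> 100
  flatted <- icadenoise:::set_timeseries_matrix(img, rep(1, nrow(X)) %o% mu)
  d100 <- delta_std_map(img, flatted)
  expect_equal(unique(round(d100[img$brain_mask], 8)), 100)
  expect_error(delta_std_map(img, make_subject(cfg, 6)$image), NA)
  cfg2 <- synth_config(n_subjects = 2, dim = c(8, 8, 8), n_frames = 30, seed = 3)
  expect_error(delta_std_map(img, make_subject(cfg2, 5)$image), "grid")
})

test_that("TFCE: zero maps, single-voxel closed form, monotone in the input", {
  dm <- c(7, 7, 5)
  zero <- array(0, dm)
  expect_equal(tfce(zero), zero)
  one <- array(0, dm); one[4, 4, 3] <- 2
  v <- 2; H <- 2; E <- 0.5
  enh <- tfce(one, E = E, H = H, dh = v / 100)
  expect_equal(enh[4, 4, 3], v^(H + 1) / (H + 1), tolerance = 0.05)
  withr::with_seed(4, {
    m <- array(stats::runif(prod(dm)), dm)
    e1 <- tfce(m, dh = 0.05)
    e2 <- tfce(2 * m, dh = 0.05)
    expect_true(all(e2 >= e1 - 1e-12))
  })
})

test_that("the %dSTD group test separates maps clearly above or below the floor", {
  dm <- c(6, 6, 4)
  # 12 subjects: enough sign-flip patterns (2^12) for the 0.01 FWE level
  withr::with_seed(5, {
    above <- lapply(1:12, function(i) {
      structure(array(45 + stats::rnorm(prod(dm), sd = 0.1), dm),
                class = "delta_std_map")
    })
    below <- lapply(1:12, function(i) {
      structure(array(25 + stats::rnorm(prod(dm), sd = 0.1), dm),
                class = "delta_std_map")
    })
  })
  up <- delta_std_group_test(above, floor_percent = 35, n_perm = 199, seed = 1)
  expect_true(all(up$sig_mask))
  down <- delta_std_group_test(below, floor_percent = 35, n_perm = 199,
                               seed = 1)
  expect_false(any(down$sig_mask))
  # permutation p-values are bounded below by 1/(n_perm + 1)
  p <- up$p_map[is.finite(up$p_map)]
  expect_true(all(p >= 1 / 200 - 1e-12))
  expect_true(all(p <= 1))
  expect_error(delta_std_group_test(above[1:3], 35, 199), "at least 4")
})

test_that("probability maps count exceeding subjects", {
  dm <- c(4, 4, 3)
  hi <- structure(array(40, dm), class = "delta_std_map")
  lo <- structure(array(10, dm), class = "delta_std_map")
  expect_equal(unique(as.vector(delta_std_probability_map(list(hi), 25))), 1)
  both <- delta_std_probability_map(list(hi, lo), 25)
  expect_equal(unique(as.vector(both)), 0.5)
  expect_true(all(both >= 0 & both <= 1))
})

test_that("|%dZ| follows its closed form and flags a zero denominator", {
  withr::with_seed(6, {
    V <- 200
    z <- stats::rnorm(V) + 1
    mask <- rep(TRUE, V)
    expect_equal(percent_delta_z(z, z, mask), 0)
    expect_equal(percent_delta_z(z, 2 * z, mask), 100)
    expect_equal(percent_delta_z(z, 1.053 * z, mask), 5.3, tolerance = 1e-10)
    z0 <- c(1, -1, rep(0, V - 2))
    expect_error(percent_delta_z(z0, z, mask), "zero")
    expect_error(percent_delta_z(z, z, rep(FALSE, V)), "empty")
  })
})

test_that("ANOVA across NOIs matches the two-group t identity and handles degeneracy", {
  # identical constants: F = 0, p = 1 by the documented convention
  same <- matrix(5, nrow = 6, ncol = 3)
  r0 <- anova_across_nois(same)
  expect_equal(r0$f, 0)
  expect_equal(r0$p, 1)
  expect_true(all(r0$pairwise$p_adj >= r0$pairwise$p_raw - 1e-12))
  # two groups: F equals the squared pooled-variance two-sample t
  withr::with_seed(7, {
    a <- stats::rnorm(10); b <- stats::rnorm(10) + 1
  })
  r2 <- anova_across_nois(cbind(a, b))
  tt <- stats::t.test(a, b, var.equal = TRUE)
  expect_equal(r2$f, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(r2$p, tt$p.value, tolerance = 1e-10)
  expect_error(anova_across_nois(matrix(1, 1, 3)), ">= 2")
})

test_that("paired t test: identical inputs, degenerate differences, analytic power", {
  a <- c(1, 2, 3, 4)
  r <- paired_ttest(a, a)
  expect_equal(r$t, 0)
  expect_equal(r$p, 1)
  expect_error(paired_ttest(a, a + 2), "zero variance")
  # rejection rate over simulations matches the analytic power of the paired t
  n <- 10; shift <- 1; reps <- 1000
  crit <- stats::qt(0.975, n - 1)
  power <- 1 - stats::pt(crit, n - 1, ncp = shift * sqrt(n)) +
    stats::pt(-crit, n - 1, ncp = shift * sqrt(n))
  rej <- withr::with_seed(8, {
    mean(replicate(reps, {
      x <- stats::rnorm(n, shift)
      paired_ttest(x, rep(0, n))$p < 0.05
    }))
  })
  expect_equal(rej, power, tolerance = 0.05)
})

test_that("grayplots order tissues, normalise rows and expose global spikes", {
  cfg <- synth_config(n_subjects = 2, dim = c(14, 14, 12), n_frames = 40,
                      seed = 9)
  s <- make_subject(cfg, 4)
  g <- grayplot(s$image, s$masks)
  n_gray <- sum(s$masks$gray > 0.5 & s$image$brain_mask)
  n_white <- sum(s$masks$white > 0.5 & s$image$brain_mask)
  expect_equal(dim(g), c(n_gray + n_white, 40))
  expect_equal(attr(g, "n_gray"), n_gray)
  rs <- apply(g, 1, stats::sd)
  expect_true(all(abs(rs[rs > 0] - 1) < 1e-8))
  # inject a global spike: that column dominates
  spiked <- s$image
  spiked$voxels[, , , 20] <- spiked$voxels[, , , 20] + 50
  g2 <- grayplot(spiked, s$masks)
  colstrength <- colMeans(abs(g2))
  expect_equal(which.max(colstrength), 20L)
  # constant voxels become zero rows
  flat <- image4d(array(2, dim(s$image$voxels)),
                  brain_mask = s$image$brain_mask)
  g3 <- grayplot(flat, s$masks)
  expect_equal(max(abs(g3)), 0)
  # rendering produces a ggplot object
  p <- ggplot2::autoplot(g)
  expect_s3_class(p, "ggplot")
})
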