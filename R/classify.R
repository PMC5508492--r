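# Component classification: computable features encoding the visual criteria
# used for manual IC labelling (peripheral/speckled spatial pattern,
# high-frequency spectrum, spikes or saw-tooth time courses, venous-sinus
# signal), a fixed and a trainable noise scorer, LOSO TPR/TNR threshold
# sweeps, the optimal-threshold rule, and lesion-component overlap.

#' Spatial and temporal features of each component
#'
#' Suprathreshold spatial sets use `|z| > 2`. Per component:
#' * `edge_fraction` — fraction of suprathreshold spatial weight (sum of
#'   `|z|`) inside the brain-edge rim;
#' * `speckle_extent` — fraction of brain voxels suprathreshold;
#' * `n_clusters` — connected components (26-connectivity) of the
#'   suprathreshold set;
#' * `high_freq_fraction` — periodogram power above 0.1 Hz over total
#'   (frequency 0 removed);
#' * `spike_score` — max |first difference| over `1.4826 x` the median
#'   absolute deviation of the first differences (0 for a constant time
#'   course; if the MAD vanishes but the differences do not, the mean
#'   absolute deviation substitutes in the denominator);
#' * `sawtooth_score` — absolute skewness of the first differences (ramps
#'   with abrupt resets give strongly asymmetric differences);
#' * `csf_vessel_fraction` — like `edge_fraction` over CSF (probability
#'   > 0.5) union vessel voxels.
#'
#' @param decomp A [component_decomposition()].
#' @param masks A `tissue_masks` object on the same grid
#'   (see [make_tissue_masks()]).
#' @param z_threshold Suprathreshold cutoff on `|z|`.
#' @param hf_cutoff_hz High-frequency boundary in Hz.
#' @return A [tibble::tibble()], one row per component.
#' @export
component_features <- function(decomp, masks, z_threshold = 2,
                               hf_cutoff_hz = 0.1) {
  if (!identical(dim(masks$brain_mask), dim(decomp$mask))) {
    stop("masks grid does not match the decomposition grid")
  }
  brain <- decomp$mask
  rim_in <- masks$edge_rim[brain]
  csfves_in <- (masks$csf > 0.5 | masks$vessel)[brain]
  Vb <- sum(brain)
  K <- n_components(decomp)
  out <- lapply(seq_len(K), function(k) {
    z <- decomp$spatial_maps[k, ]
    supra <- abs(z) > z_threshold
    w <- abs(z) * supra
    tw <- sum(w)
    edge <- if (tw == 0) 0 else sum(w[rim_in]) / tw
    csfv <- if (tw == 0) 0 else sum(w[csfves_in]) / tw
    speck <- sum(supra) / Vb
    ncl <- if (!any(supra)) 0L else {
      max(label_components(unmask(supra, brain, fill = FALSE)))
    }
    tc <- decomp$timecourses[, k]
    hf <- if (stats::sd(tc) == 0) 0 else {
      high_freq_power_fraction(tc, decomp$tr_seconds, hf_cutoff_hz)
    }
    d <- diff(tc)
    if (max(abs(d)) == 0) {
      spike <- 0
    } else {
      denom <- stats::mad(d) # 1.4826 * median(|d - median(d)|)
      if (denom == 0) denom <- 1.4826 * mean(abs(d - stats::median(d)))
      spike <- if (denom == 0) 0 else max(abs(d)) / denom
    }
    saw <- abs(skewness(d))
    tibble::tibble(component = k, edge_fraction = edge, speckle_extent = speck,
                   n_clusters = as.integer(ncl), high_freq_fraction = hf,
                   spike_score = spike, sawtooth_score = saw,
                   csf_vessel_fraction = csfv)
  })
  do.call(rbind, out)
}

feature_columns <- function(mode = c("all-noise", "motion-only")) {
  mode <- match.arg(mode)
  if (mode == "motion-only") {
    c("edge_fraction", "spike_score", "high_freq_fraction")
  } else {
    c("edge_fraction", "speckle_extent", "n_clusters", "high_freq_fraction",
      "spike_score", "sawtooth_score", "csf_vessel_fraction")
  }
}

# Normalise raw features to [0, 1] for the fixed scorer.
normalise_features <- function(features) {
  tibble::tibble(
    component = features$component,
    edge_fraction = features$edge_fraction,
    speckle_extent = pmin(features$speckle_extent / 0.25, 1),
    n_clusters = pmin(pmax(features$n_clusters - 1, 0) / 9, 1),
    high_freq_fraction = features$high_freq_fraction,
    spike_score = pmin(features$spike_score / 10, 1),
    sawtooth_score = pmin(features$sawtooth_score / 3, 1),
    csf_vessel_fraction = features$csf_vessel_fraction)
}

#' Score components as noise with fixed, interpretable weights
#'
#' Monotone weighted combination of the normalised features, scaled to
#' `[0, 100]` (higher = more noise-like). In `motion-only` mode (AROMA-style
#' focus on motion) only `edge_fraction`, `spike_score` and
#' `high_freq_fraction` contribute; `all-noise` mode (FIX-style removal of
#' every noise family) uses all seven features. A component whose noise
#' features are all zero scores 0.
#'
#' @param features A [component_features()] table.
#' @param mode `"all-noise"` or `"motion-only"`.
#' @param weights Optional named weights overriding the defaults.
#' @return A [tibble::tibble()] with columns `component`, `score`, `mode`.
#' @export
noise_score <- function(features, mode = c("all-noise", "motion-only"),
                        weights = NULL) {
  mode <- match.arg(mode)
  defaults <- c(edge_fraction = 0.25, speckle_extent = 0.15, n_clusters = 0.10,
                high_freq_fraction = 0.15, spike_score = 0.15,
                sawtooth_score = 0.05, csf_vessel_fraction = 0.15)
  cols <- feature_columns(mode)
  w <- defaults[cols]
  if (!is.null(weights)) {
    if (!all(is.finite(weights))) stop("weights must be finite")
    w[names(weights)[names(weights) %in% cols]] <-
      weights[names(weights) %in% cols]
  }
  nf <- normalise_features(features)
  fm <- as.matrix(nf[, cols, drop = FALSE])
  score <- 100 * as.vector(fm %*% w) / sum(w)
  tibble::tibble(component = features$component,
                 score = pmin(pmax(score, 0), 100), mode = mode)
}

#' Train a noise scorer on labelled feature tables
#'
#' Regularised linear discriminant on the feature set of the requested mode:
#' features are standardised, the pooled within-class covariance is ridged
#' (`lambda x` mean diagonal), and the discriminant projection is mapped to
#' `[0, 100]` by a logistic centred between the class means. Deterministic
#' given the data.
#'
#' @param feature_tables List of [component_features()] tables (one per
#'   subject) or a single table.
#' @param label_sets Matching list of label tibbles with columns `component`,
#'   `label` (`"signal"` / `"noise"`).
#' @param mode Scoring mode, as in [noise_score()].
#' @param lambda Ridge fraction for the pooled covariance.
#' @return An object of class `ic_scorer`; use [predict_scores()] to score
#'   new feature tables.
#' @export
train_scorer <- function(feature_tables, label_sets,
                         mode = c("all-noise", "motion-only"), lambda = 0.1) {
  mode <- match.arg(mode)
  if (is.data.frame(feature_tables)) feature_tables <- list(feature_tables)
  if (is.data.frame(label_sets)) label_sets <- list(label_sets)
  stopifnot(length(feature_tables) == length(label_sets))
  cols <- feature_columns(mode)
  X <- do.call(rbind, lapply(feature_tables, function(f) {
    as.matrix(f[, cols, drop = FALSE])
  }))
  y <- unlist(lapply(label_sets, function(l) l$label))
  if (length(unique(y)) < 2) {
    stop("training data must contain both signal and noise components")
  }
  mu <- colMeans(X)
  sdv <- apply(X, 2, stats::sd)
  sdv[sdv == 0] <- 1
  Xs <- sweep(sweep(X, 2, mu), 2, sdv, `/`)
  noise <- y == "noise"
  m1 <- colMeans(Xs[noise, , drop = FALSE])
  m0 <- colMeans(Xs[!noise, , drop = FALSE])
  cov_pool <- function(M) {
    if (nrow(M) < 2) return(matrix(0, ncol(M), ncol(M)))
    stats::cov(M) * (nrow(M) - 1)
  }
  S <- (cov_pool(Xs[noise, , drop = FALSE]) +
          cov_pool(Xs[!noise, , drop = FALSE])) / max(length(y) - 2, 1)
  S <- S + diag(lambda * mean(diag(S)) + 1e-8, ncol(S))
  wvec <- solve(S, m1 - m0)
  proj1 <- sum(m1 * wvec); proj0 <- sum(m0 * wvec)
  center <- (proj1 + proj0) / 2
  scale <- max((proj1 - proj0) / 4, 1e-8)
  structure(list(mode = mode, columns = cols, mu = mu, sd = sdv, w = wvec,
                 center = center, scale = scale),
            class = "ic_scorer")
}

#' Score a feature table with a trained scorer
#'
#' @param scorer An [train_scorer()] object.
#' @param features A [component_features()] table.
#' @return A [tibble::tibble()] with columns `component`, `score`, `mode`.
#' @export
predict_scores <- function(scorer, features) {
  X <- as.matrix(features[, scorer$columns, drop = FALSE])
  Xs <- sweep(sweep(X, 2, scorer$mu), 2, scorer$sd, `/`)
  p <- as.vector(Xs %*% scorer$w)
  score <- 100 * stats::plogis((p - scorer$center) / scorer$scale)
  tibble::tibble(component = features$component, score = score,
                 mode = scorer$mode)
}

#' TPR and TNR of a predicted labelling against the truth
#'
#' TPR is the percentage of true signal components predicted signal; TNR the
#' percentage of true noise components predicted noise. Invariant to
#' component ordering.
#'
#' @param predicted,truth Label tibbles (columns `component`, `label`) or
#'   bare character vectors over the same components.
#' @return Named numeric `c(tpr, tnr)` in percent.
#' @export
evaluate_tpr_tnr <- function(predicted, truth) {
  lab <- function(x) {
    if (is.data.frame(x)) x$label[order(x$component)] else as.character(x)
  }
  p <- lab(predicted); t <- lab(truth)
  if (length(p) != length(t)) stop("predicted and truth must cover the same components")
  n_sig <- sum(t == "signal"); n_noi <- sum(t == "noise")
  if (n_sig == 0 || n_noi == 0) {
    stop("TPR/TNR undefined: truth must contain both signal and noise components")
  }
  c(tpr = 100 * sum(t == "signal" & p == "signal") / n_sig,
    tnr = 100 * sum(t == "noise" & p == "noise") / n_noi)
}

#' Leave-one-subject-out threshold sweep
#'
#' For each fold, a scorer is trained on all other subjects, the held-out
#' subject's components are scored, and the scores are binarised at each
#' threshold (`score >= threshold` predicts noise). Per-subject TPR/TNR are
#' aggregated to mean and median per threshold. Folds whose truth has a
#' single class are excluded from the statistics and reported in the
#' `excluded` attribute.
#'
#' @param feature_tables,label_sets Per-subject lists as in [train_scorer()].
#' @param thresholds Score thresholds to sweep.
#' @param mode Scoring mode.
#' @return A tibble of class `threshold_sweep` with columns `threshold`,
#'   `mean_tpr`, `median_tpr`, `mean_tnr`, `median_tnr` (percent).
#' @export
loso_sweep <- function(feature_tables, label_sets,
                       thresholds = c(1, 2, 5, 10, 20, 30, 40, 50),
                       mode = c("all-noise", "motion-only")) {
  mode <- match.arg(mode)
  n <- length(feature_tables)
  if (n < 2) stop("LOSO needs at least 2 subjects")
  tpr <- matrix(NA_real_, n, length(thresholds))
  tnr <- matrix(NA_real_, n, length(thresholds))
  excluded <- integer(0)
  for (i in seq_len(n)) {
    truth <- label_sets[[i]]$label
    if (length(unique(truth)) < 2) {
      excluded <- c(excluded, i)
      next
    }
    scorer <- train_scorer(feature_tables[-i], label_sets[-i], mode = mode)
    sc <- predict_scores(scorer, feature_tables[[i]])$score
    for (j in seq_along(thresholds)) {
      pred <- ifelse(sc >= thresholds[j], "noise", "signal")
      r <- evaluate_tpr_tnr(pred, truth)
      tpr[i, j] <- r[["tpr"]]; tnr[i, j] <- r[["tnr"]]
    }
  }
  if (length(excluded) > 0) {
    message("LOSO: excluded single-class subjects: ",
            paste(excluded, collapse = ", "))
  }
  sweep_tbl <- threshold_sweep(
    thresholds = thresholds,
    mean_tpr = apply(tpr, 2, mean, na.rm = TRUE),
    median_tpr = apply(tpr, 2, stats::median, na.rm = TRUE),
    mean_tnr = apply(tnr, 2, mean, na.rm = TRUE),
    median_tnr = apply(tnr, 2, stats::median, na.rm = TRUE))
  attr(sweep_tbl, "excluded") <- excluded
  sweep_tbl
}

#' Construct a threshold sweep table
#'
#' @param thresholds Ordered thresholds.
#' @param mean_tpr,median_tpr,mean_tnr,median_tnr Percentages in `[0, 100]`.
#' @return A tibble of class `threshold_sweep`.
#' @export
threshold_sweep <- function(thresholds, mean_tpr, median_tpr, mean_tnr,
                            median_tnr) {
  pct <- c(mean_tpr, median_tpr, mean_tnr, median_tnr)
  if (any(pct < -1e-9 | pct > 100 + 1e-9, na.rm = TRUE)) {
    stop("TPR/TNR values must be percentages in [0, 100]")
  }
  out <- tibble::tibble(threshold = as.numeric(thresholds),
                        mean_tpr = as.numeric(mean_tpr),
                        median_tpr = as.numeric(median_tpr),
                        mean_tnr = as.numeric(mean_tnr),
                        median_tnr = as.numeric(median_tnr))
  class(out) <- c("threshold_sweep", class(out))
  out
}

#' Select the optimal classification threshold
#'
#' Among thresholds whose mean TPR exceeds `tpr_floor`, returns the one with
#' the highest mean TNR, provided that maximum is at least `tnr_min`;
#' otherwise no threshold qualifies and `NA` is returned. Ties go to the
#' largest threshold.
#'
#' @param sweep A [threshold_sweep()].
#' @param tpr_floor Mean TPR must be strictly above this (percent).
#' @param tnr_min Minimum acceptable mean TNR (percent).
#' @return The selected threshold, or `NA_real_` if none qualifies.
#' @export
select_optimal_threshold <- function(sweep, tpr_floor = 90, tnr_min = 10) {
  if (nrow(sweep) == 0) return(NA_real_)
  ok <- !is.na(sweep$mean_tpr) & sweep$mean_tpr > tpr_floor
  if (!any(ok)) return(NA_real_)
  cand <- sweep[ok, ]
  best <- max(cand$mean_tnr, na.rm = TRUE)
  if (!is.finite(best) || best < tnr_min) return(NA_real_)
  max(cand$threshold[cand$mean_tnr == best])
}

#' Overlap between a component's suprathreshold set and a lesion
#'
#' @param component_mask 3D logical suprathreshold set (non-empty).
#' @param lesion_mask 3D logical lesion mask on the same grid.
#' @return Fraction of component voxels inside the lesion, in `[0, 1]`.
#' @export
lesion_overlap <- function(component_mask, lesion_mask) {
  if (!identical(dim(component_mask), dim(lesion_mask))) {
    stop("component and lesion masks must share a grid")
  }
  n <- sum(component_mask)
  if (n == 0) stop("component suprathreshold set is empty")
  sum(component_mask & lesion_mask) / n
}

#' Restrict a label set to the noise families a mode targets
#'
#' All-noise mode keeps the labels as they are. Motion-only mode relabels as
#' noise only the components whose subtype is `"motion"` (everything else,
#' including physiological and vascular noise, counts as signal for that
#' mode); label sets without subtype information are returned unchanged.
#'
#' @param label_set Label tibble with columns `component`, `label` and
#'   optionally `subtype`.
#' @param mode `"all-noise"` or `"motion-only"`.
#' @return A label tibble.
#' @export
labels_for_mode <- function(label_set, mode = c("all-noise", "motion-only")) {
  mode <- match.arg(mode)
  if (mode == "all-noise" || !"subtype" %in% names(label_set) ||
      all(is.na(label_set$subtype))) {
    return(label_set)
  }
  label_set$label <- ifelse(
    !is.na(label_set$subtype) & label_set$subtype == "motion",
    "noise", "signal")
  label_set
}

#' Rule-based component labelling from the manual criteria
#'
#' Primary criteria: predominantly peripheral suprathreshold weight, or a
#' speckled pattern covering roughly a quarter or more of the brain.
#' Secondary criteria (any two): predominantly high-frequency spectrum,
#' spiky or saw-tooth time course, venous-sinus/CSF weight.
#'
#' @param features A [component_features()] table.
#' @return A label tibble (`component`, `label`, `provenance = "rule"`).
#' @export
rule_label <- function(features) {
  primary <- features$edge_fraction > 0.5 |
    (features$speckle_extent >= 0.25 & features$n_clusters >= 5)
  secondary <- (features$high_freq_fraction > 0.5) +
    (features$spike_score > 6 | features$sawtooth_score > 1.5) +
    (features$csf_vessel_fraction > 0.5)
  noise <- primary | secondary >= 2
  tibble::tibble(component = features$component,
                 label = ifelse(noise, "noise", "signal"),
                 provenance = "rule")
}
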