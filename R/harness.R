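# Experiment orchestration: configuration, the one-command synthetic study
# runner (simulate -> strategies -> dual regression -> metrics -> report),
# and TSV plumbing for threshold-sweep tables including the worked-example
# checker for published FIX benchmark sweeps.

#' Configuration of a full synthetic experiment
#'
#' @param synth A [synth_config()] describing the cohort.
#' @param strategies Denoising strategies to evaluate (`"fix"`, `"aroma"`).
#' @param thresholds Threshold sweep list for the LOSO evaluation.
#' @param n_templates Number of NOI atlas templates.
#' @param mask_thresholds RSN-mask thresholds for identifiability.
#' @param n_splits Split-half reproducibility splits.
#' @param n_perm Permutations for the %dSTD group test.
#' @param decomposition `"ground_truth"` (exact wrap of the injected sources;
#'   fast and free of ICA recovery error) or `"ica"` (run [decompose()]).
#' @param run_group_test Run the permutation %dSTD group test (slowest part).
#' @param seed Master seed; every stage derives a named substream from it.
#' @param out_dir Optional output directory for artefacts.
#' @return A list of class `experiment_config`.
#' @export
experiment_config <- function(synth = synth_config(),
                              strategies = c("fix", "aroma"),
                              thresholds = c(1, 2, 5, 10, 20, 30, 40, 50),
                              n_templates = 20,
                              mask_thresholds = c(1.5, 2.3, 3.1),
                              n_splits = 100,
                              n_perm = 200,
                              decomposition = c("ground_truth", "ica"),
                              run_group_test = FALSE,
                              seed = 1L,
                              out_dir = NULL) {
  decomposition <- match.arg(decomposition)
  strategies <- match.arg(strategies, c("fix", "aroma"), several.ok = TRUE)
  if (is.unsorted(thresholds)) stop("thresholds must be sorted ascending")
  structure(list(synth = synth, strategies = strategies,
                 thresholds = thresholds, n_templates = n_templates,
                 mask_thresholds = mask_thresholds, n_splits = n_splits,
                 n_perm = n_perm, decomposition = decomposition,
                 run_group_test = run_group_test, seed = as.integer(seed),
                 out_dir = out_dir),
            class = "experiment_config")
}

#' Read / write an experiment config as YAML
#'
#' @param path YAML file path.
#' @return [experiment_config()] (read) or `path` invisibly (write).
#' @export
read_experiment_config <- function(path) {
  y <- yaml::read_yaml(path)
  sc <- do.call(synth_config, y$synth)
  y$synth <- sc
  do.call(experiment_config, y)
}

#' @rdname read_experiment_config
#' @param config An [experiment_config()].
#' @export
write_experiment_config <- function(config, path) {
  y <- unclass(config)
  y$synth <- lapply(unclass(y$synth), function(v) {
    if (is.numeric(v) && !is.null(names(v))) as.list(v) else v
  })
  yaml::write_yaml(y, path)
  invisible(path)
}

#' Run the full synthetic study
#'
#' Simulates a cohort, classifies components (LOSO threshold sweep and
#' optimal-threshold selection per strategy), cleans every subject
#' non-aggressively with the trained scorer, runs template-based dual
#' regression on uncorrected and corrected data, and computes the metric
#' suite. Deterministic given the master seed.
#'
#' @param config An [experiment_config()].
#' @return A list of class `study_report`; if `config$out_dir` is set, a JSON
#'   report and TSV tables are written there.
#' @export
run_experiment <- function(config) {
  log_stage <- function(...) message(sprintf(...))
  cfg <- config$synth
  log_stage("simulate: %d subjects on %dx%dx%d grid", cfg$n_subjects,
            cfg$dim[1], cfg$dim[2], cfg$dim[3])
  cohort <- make_cohort(cfg)
  atlas <- make_noi_atlas(cohort, config$n_templates,
                          seed = derive_seed(config$seed, "atlas"))
  masks <- cohort[[1]]$masks

  log_stage("decompose (%s) + features", config$decomposition)
  decomps <- lapply(seq_along(cohort), function(i) {
    s <- cohort[[i]]
    if (config$decomposition == "ground_truth") {
      wrap_ground_truth(s)
    } else {
      d <- decompose(gaussian_smooth(s$image, 5), k = "auto",
                     seed = derive_seed(config$seed, "ica", i))
      mt <- match_components(d, s$truth$signal_maps)
      lab <- tibble::tibble(
        component = seq_len(n_components(d)),
        label = ifelse(seq_len(n_components(d)) %in%
                         mt$component[mt$r > 0.5], "signal", "noise"),
        subtype = NA_character_, provenance = "rule")
      attr(d, "labels") <- lab
      d
    }
  })
  features <- lapply(decomps, component_features, masks = masks)
  labels <- lapply(decomps, function(d) attr(d, "labels"))

  report <- list(seed = config$seed, decomposition = config$decomposition,
                 strategies = list())
  dr_orig <- NULL
  delta_z_by_strategy <- list()

  for (strategy in config$strategies) {
    mode <- if (strategy == "fix") "all-noise" else "motion-only"
    log_stage("strategy %s: LOSO sweep (%d thresholds)", strategy,
              length(config$thresholds))
    mode_labels <- lapply(labels, labels_for_mode, mode = mode)
    sweep_tbl <- loso_sweep(features, mode_labels,
                            thresholds = config$thresholds, mode = mode)
    thr <- select_optimal_threshold(sweep_tbl)
    thr_used <- if (is.na(thr)) 50 else thr
    log_stage("strategy %s: selected threshold %s", strategy,
              ifelse(is.na(thr), "none (fallback 50)", format(thr)))
    scorer <- train_scorer(features, mode_labels, mode = mode)

    log_stage("strategy %s: cleanup + dual regression", strategy)
    cleanups <- lapply(seq_along(cohort), function(i) {
      run_strategy(cohort[[i]]$image, masks, strategy = strategy,
                   scorer = scorer, threshold = thr_used,
                   decomp = decomps[[i]],
                   seed = derive_seed(config$seed, "clean", i))
    })
    if (is.null(dr_orig)) {
      dr_orig <- lapply(seq_along(cohort), function(i) {
        template_dual_regression(cleanups[[i]]$preprocessed, atlas, subject = i)
      })
    }
    dr_clean <- lapply(seq_along(cohort), function(i) {
      template_dual_regression(cleanups[[i]]$cleaned, atlas, subject = i)
    })

    n_sig <- cfg$k_signal
    matched <- seq_len(n_sig)
    ident <- function(drs) {
      vapply(drs, function(r) {
        mean(vapply(matched, function(k) {
          rsn_identifiability(r$zmaps[k, ], atlas$templates[, , , k][atlas$brain_mask],
                              mask_threshold = 2.3)
        }, numeric(1)))
      }, numeric(1))
    }
    ident_orig <- ident(dr_orig)
    ident_clean <- ident(dr_clean)

    repro_orig <- split_half_reproducibility(
      dr_orig, atlas$gray_matter, n_splits = config$n_splits,
      seed = derive_seed(config$seed, "splits", strategy, 0))
    repro_clean <- split_half_reproducibility(
      dr_clean, atlas$gray_matter, n_splits = config$n_splits,
      seed = derive_seed(config$seed, "splits", strategy, 1))

    tdof <- vapply(cleanups, function(cl) {
      tdof_loss_percent(cl$tdof_lost, cl$tdof_total)
    }, numeric(1))

    dstd <- lapply(seq_along(cohort), function(i) {
      delta_std_map(cleanups[[i]]$preprocessed, cleanups[[i]]$cleaned)
    })
    prob_map <- delta_std_probability_map(dstd, 25)
    group_test <- if (config$run_group_test) {
      delta_std_group_test(dstd, floor_percent = 35, n_perm = config$n_perm,
                           seed = derive_seed(config$seed, "perm", strategy))
    } else NULL

    noi_masks <- lapply(seq_len(config$n_templates), function(k) {
      abs(atlas$templates[, , , k][atlas$brain_mask]) > 2.3
    })
    dz <- t(vapply(seq_along(cohort), function(i) {
      vapply(seq_len(config$n_templates), function(k) {
        so <- sum(dr_orig[[i]]$zmaps[k, noi_masks[[k]]])
        if (so == 0) return(NA_real_)
        percent_delta_z(dr_orig[[i]]$zmaps[k, ], dr_clean[[i]]$zmaps[k, ],
                        noi_masks[[k]])
      }, numeric(1))
    }, numeric(config$n_templates)))
    delta_z_by_strategy[[strategy]] <- dz

    report$strategies[[strategy]] <- list(
      sweep = sweep_tbl, selected_threshold = thr,
      threshold_used = thr_used,
      n_removed = vapply(cleanups, function(cl) cl$tdof_lost, integer(1)),
      tdof_loss_percent = tdof,
      variance_removed = vapply(seq_along(cohort), function(i) {
        variance_fraction_of(decomps[[i]], cleanups[[i]]$removed_ids)
      }, numeric(1)),
      identifiability_original = ident_orig,
      identifiability_cleaned = ident_clean,
      reproducibility_original = repro_orig,
      reproducibility_cleaned = repro_clean,
      delta_std_maps = dstd, probability_map = prob_map,
      group_test = group_test, delta_z = dz,
      cleanups = cleanups, dualreg = dr_clean)
  }
  report$dualreg_original <- dr_orig
  report$atlas <- atlas

  if (length(delta_z_by_strategy) >= 1) {
    report$delta_z_anova <- lapply(delta_z_by_strategy, function(dz) {
      ok <- colSums(!is.finite(dz)) == 0
      if (sum(ok) >= 2) anova_across_nois(dz[, ok, drop = FALSE]) else NULL
    })
  }
  if (all(c("fix", "aroma") %in% names(delta_z_by_strategy))) {
    a <- rowMeans(delta_z_by_strategy$fix, na.rm = TRUE)
    b <- rowMeans(delta_z_by_strategy$aroma, na.rm = TRUE)
    report$strategy_paired_test <- tryCatch(paired_ttest(a, b),
                                            error = function(e) NULL)
  }
  class(report) <- "study_report"
  if (!is.null(config$out_dir)) write_study_report(report, config$out_dir)
  report
}

# Serialise the numeric core of a study report to JSON + TSVs.
write_study_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  core <- list(seed = report$seed, decomposition = report$decomposition)
  for (nm in names(report$strategies)) {
    st <- report$strategies[[nm]]
    write_sweep_tsv(st$sweep, file.path(dir, sprintf("sweep_%s.tsv", nm)))
    core[[nm]] <- list(
      selected_threshold = st$selected_threshold,
      threshold_used = st$threshold_used,
      mean_tdof_loss_percent = mean(st$tdof_loss_percent),
      mean_variance_removed = mean(st$variance_removed),
      mean_identifiability_original = mean(st$identifiability_original),
      mean_identifiability_cleaned = mean(st$identifiability_cleaned),
      mean_pseudo_z_original = mean(st$reproducibility_original$mean_pseudo_z,
                                    na.rm = TRUE),
      mean_pseudo_z_cleaned = mean(st$reproducibility_cleaned$mean_pseudo_z,
                                   na.rm = TRUE),
      mean_abs_delta_z = mean(st$delta_z, na.rm = TRUE))
  }
  jsonlite::write_json(core, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(dir)
}

#' Write / read a threshold sweep as TSV
#'
#' Tab-delimited with a header row (`threshold`, `mean_tpr`, `median_tpr`,
#' `mean_tnr`, `median_tnr`), one row per threshold.
#'
#' @param sweep A [threshold_sweep()].
#' @param path TSV path.
#' @return `path` (write) or a `threshold_sweep` (read).
#' @export
write_sweep_tsv <- function(sweep, path) {
  utils::write.table(as.data.frame(sweep), path, sep = "\t",
                     row.names = FALSE, col.names = TRUE, quote = FALSE)
  invisible(path)
}

#' @rdname write_sweep_tsv
#' @export
read_sweep_tsv <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  need <- c("threshold", "mean_tpr", "median_tpr", "mean_tnr", "median_tnr")
  missing_cols <- setdiff(need, names(d))
  if (length(missing_cols) > 0) {
    stop("malformed sweep TSV: missing column(s) ",
         paste(missing_cols, collapse = ", "))
  }
  for (cn in need) {
    if (!is.numeric(d[[cn]])) {
      stop(sprintf("malformed sweep TSV: column `%s` is not numeric", cn))
    }
  }
  threshold_sweep(d$threshold, d$mean_tpr, d$median_tpr, d$mean_tnr,
                  d$median_tnr)
}

#' Apply the optimal-threshold rule to a sweep table on disk
#'
#' Reads a TSV threshold sweep (e.g. the packaged benchmark sweeps of
#' generic- and patient-trained FIX classifiers on an acute stroke cohort,
#' under `inst/extdata/`), applies [select_optimal_threshold()] and prints a
#' rule trace.
#'
#' @param x TSV path or a `threshold_sweep`.
#' @param tpr_floor,tnr_min Rule parameters (percent).
#' @param quiet Suppress the trace.
#' @return The selected threshold, or `NA_real_` when no threshold
#'   qualifies.
#' @export
check_sweep_table <- function(x, tpr_floor = 90, tnr_min = 10, quiet = FALSE) {
  sweep_tbl <- if (is.character(x)) read_sweep_tsv(x) else x
  ok <- !is.na(sweep_tbl$mean_tpr) & sweep_tbl$mean_tpr > tpr_floor
  sel <- select_optimal_threshold(sweep_tbl, tpr_floor, tnr_min)
  if (!quiet) {
    for (i in seq_len(nrow(sweep_tbl))) {
      message(sprintf(
        "threshold %4g: mean TPR %5.1f%% %s floor %g; mean TNR %5.1f%%%s",
        sweep_tbl$threshold[i], sweep_tbl$mean_tpr[i],
        ifelse(ok[i], ">", "<="), tpr_floor, sweep_tbl$mean_tnr[i],
        ifelse(!is.na(sel) && sweep_tbl$threshold[i] == sel,
               "  <- selected", "")))
    }
    if (is.na(sel)) {
      message(sprintf(
        "no threshold with mean TPR > %g%% reaches mean TNR >= %g%%: none selected",
        tpr_floor, tnr_min))
    }
  }
  sel
}
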