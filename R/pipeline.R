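#' Study configuration
#'
#' Bundles every parameter of the end-to-end robustness study: phantom cohort,
#' segmentation, discretization, the two simulated observers and the master
#' seed. Every random draw of [run_study()] derives from `seed`.
#'
#' @param n_patients Cohort size (default 43).
#' @param base_spec Template [phantom_spec()].
#' @param size_range_ml Tumor volume range (ml).
#' @param small_fraction Proportion of tumors below the analyzability floor.
#' @param jitter_mm Observer seed-click jitter magnitude (mm); 0 makes the
#'   two observers identical end to end.
#' @param seg_config A [segmentation_config()]; when its `adaptive_coeffs`
#'   are `NULL`, [run_study()] calibrates them on sphere phantoms matching
#'   the cohort blur.
#' @param disc_config A [discretization_config()].
#' @param seed Master RNG seed.
#' @return Object of class `study_config`.
#' @export
study_config <- function(n_patients = 43, base_spec = phantom_spec(),
                         size_range_ml = c(1, 60), small_fraction = 0.3,
                         jitter_mm = 4, seg_config = segmentation_config(),
                         disc_config = discretization_config(), seed = 1L) {
  structure(list(n_patients = n_patients, base_spec = base_spec,
                 size_range_ml = size_range_ml,
                 small_fraction = small_fraction, jitter_mm = jitter_mm,
                 seg_config = seg_config, disc_config = disc_config,
                 seed = as.integer(seed)),
            class = "study_config")
}

#' Run the full robustness study on a synthetic cohort
#'
#' Generates the phantom cohort, segments every tumor with the three
#' delineation methods for two simulated observers, extracts the feature
#' vectors of eligible VOIs, and computes the agreement analysis: correlation
#' grouping and index selection, inter-method variability (Friedman and
#' pairwise Wilcoxon), inter-observer reproducibility (ICC with Landis-Koch
#' labels) and Bland-Altman volume comparisons. Patients whose VOI fails the
#' 64-voxel floor under a method are excluded from that method; the
#' statistical tables use the complete cases (analyzable under all three
#' methods and both observers). Any segmentation failure is logged and
#' treated as an exclusion rather than aborting the run. Deterministic given
#' `config$seed`.
#'
#' @param config A [study_config()].
#' @param verbose Print per-patient progress.
#' @return Object of class `study_report`: `features` (all feature rows),
#'   `exclusion_counts`, `n_complete`, `complete_patients`, `groups`,
#'   `selected`, `variability`, `reproducibility`, `bland_altman`,
#'   `exclusion_log`, `adaptive_coeffs`, `config`.
#' @export
run_study <- function(config = study_config(), verbose = FALSE) {
  seeds <- derive_seeds(config$seed, 2L)
  cohort_seed <- seeds[1]
  obs_seeds <- matrix(derive_seeds(seeds[2], 2L * config$n_patients),
                      ncol = 2)
  seg <- config$seg_config
  if (is.null(seg$adaptive_coeffs)) {
    coeffs <- calibrate_adaptive_thresholds(
      blur_fwhm_mm = config$base_spec$blur_fwhm_mm,
      base_spec = config$base_spec, config = seg)
    seg$adaptive_coeffs <- unname(coeffs)
  }
  cohort <- generate_cohort(config$n_patients, config$base_spec,
                            config$size_range_ml, config$small_fraction,
                            seed = cohort_seed)
  rows <- list()
  log <- list()
  for (i in seq_along(cohort)) {
    p <- cohort[[i]]
    if (verbose) message("patient ", p$patient)
    for (o in 1:2) {
      obs_id <- paste0("obs", o)
      act <- try(simulate_observer(p$seed_point, config$jitter_mm,
                                   obs_seeds[i, o], p$true_mask$mask,
                                   spacing = p$volume$spacing,
                                   observer = obs_id), silent = TRUE)
      for (m in SEGMENTATION_METHODS) {
        status <- "ok"
        feat <- NULL
        if (inherits(act, "try-error")) {
          status <- "seed_failure"
        } else {
          mask <- try(segment(p$volume, act$seed_point, m, seg, obs_id),
                      silent = TRUE)
          if (inherits(mask, "try-error")) {
            status <- "segmentation_error"
          } else if (!check_min_volume(mask)$eligible) {
            status <- "too_small"
          } else {
            feat <- try(extract_features(p$volume, mask, config$disc_config,
                                         patient = p$patient), silent = TRUE)
            if (inherits(feat, "try-error")) {
              status <- "feature_error"
              feat <- NULL
            }
          }
        }
        log[[length(log) + 1]] <- data.frame(
          patient = p$patient, method = m, observer = obs_id,
          status = status, stringsAsFactors = FALSE)
        if (!is.null(feat)) rows[[length(rows) + 1]] <- feat
      }
    }
  }
  features <- do.call(rbind, rows)
  exclusion_log <- do.call(rbind, log)
  excl <- vapply(SEGMENTATION_METHODS, function(m) {
    bad <- exclusion_log$method == m & exclusion_log$status != "ok"
    length(unique(exclusion_log$patient[bad]))
  }, integer(1))
  ok_tab <- table(features$patient)
  complete <- names(ok_tab)[ok_tab == 6L]
  report <- list(features = features, exclusion_counts = excl,
                 n_complete = length(complete), complete_patients = complete,
                 exclusion_log = exclusion_log,
                 adaptive_coeffs = seg$adaptive_coeffs, config = config)
  if (length(complete) >= 5) {
    report <- c(report, study_statistics(features, complete))
  } else {
    warning("fewer than 5 complete cases; statistical tables not computed")
  }
  structure(report, class = "study_report")
}

## The statistical tables of a study, computed on the complete cases.
study_statistics <- function(features, complete) {
  cc <- features[features$patient %in% complete, ]
  tex <- texture_feature_names()
  ## correlation analysis: observer 1, the three methods stacked
  base <- cc[cc$observer == "obs1", ]
  frac_na <- vapply(base[tex], function(v) mean(!is.finite(v)), numeric(1))
  usable <- tex[frac_na <= 0.5]
  if (length(usable) < length(tex))
    warning("dropping features flagged missing in >50% of VOIs: ",
            paste(setdiff(tex, usable), collapse = ", "))
  r_tex <- pearson_matrix(base, usable)
  groups <- extract_correlated_groups(r_tex, threshold = 0.8)
  r_std <- pearson_matrix(base, c(usable, "SUVmax", "MTV"))
  selected <- select_independent_indices(groups, r_std, threshold = 0.8)
  table_feats <- c("SUVmax", "MTV", selected)
  ## per (patient, method, observer) value lookup, aligned on sorted patients
  val <- function(f, m, o) {
    sub <- cc[cc$method == m & cc$observer == o, c("patient", f)]
    sub[[f]][order(sub$patient)]
  }
  meth <- SEGMENTATION_METHODS
  variability <- do.call(rbind, lapply(table_feats, function(f) {
    mat <- sapply(meth, function(m) val(f, m, "obs1"))
    keep <- rowSums(is.finite(mat)) == 3
    mat <- mat[keep, , drop = FALSE]
    if (nrow(mat) < 2 || all(apply(mat, 1, function(r) length(unique(r)) == 1))) {
      fr <- list(statistic = 0, p_value = 1)
    } else fr <- friedman_test(mat)
    pw <- combn(meth, 2, simplify = FALSE)
    pv <- vapply(pw, function(pr) {
      wilcoxon_signed_rank(mat[, pr[1]], mat[, pr[2]])$p_value
    }, numeric(1))
    data.frame(feature = f, friedman_p = fr$p_value,
               p_FIXED40_vs_ADAPTIVE = pv[[1]],
               p_FIXED40_vs_GRADIENT = pv[[2]],
               p_ADAPTIVE_vs_GRADIENT = pv[[3]],
               n = nrow(mat), stringsAsFactors = FALSE)
  }))
  reproducibility <- do.call(rbind, lapply(table_feats, function(f) {
    do.call(rbind, lapply(meth, function(m) {
      a <- val(f, m, "obs1"); b <- val(f, m, "obs2")
      keep <- is.finite(a) & is.finite(b)
      icc <- if (sum(keep) >= 3) icc_agreement(a[keep], b[keep]) else NA_real_
      data.frame(feature = f, method = m, icc = icc,
                 label = landis_koch_label(icc), n = sum(keep),
                 stringsAsFactors = FALSE)
    }))
  }))
  pairs <- list(c("GRADIENT_EDGE", "FIXED40"), c("ADAPTIVE_SBR", "FIXED40"),
                c("GRADIENT_EDGE", "ADAPTIVE_SBR"))
  ba <- lapply(pairs, function(pr) {
    bland_altman(val("MTV", pr[1], "obs1"), val("MTV", pr[2], "obs1"))
  })
  names(ba) <- vapply(pairs, paste, character(1), collapse = "_minus_")
  list(groups = groups, selected = selected, variability = variability,
       reproducibility = reproducibility, bland_altman = ba)
}

#' @export
print.study_report <- function(x, ...) {
  cat("<study_report>\n")
  cat(sprintf("  patients: %d, complete cases: %d\n",
              x$config$n_patients, x$n_complete))
  cat("  exclusions per method: ",
      paste(names(x$exclusion_counts), x$exclusion_counts,
            sep = "=", collapse = ", "), "\n")
  if (!is.null(x$selected))
    cat("  selected indices: ", paste(x$selected, collapse = ", "), "\n")
  if (!is.null(x$bland_altman)) {
    for (nm in names(x$bland_altman))
      cat(sprintf("  MTV bias %s: %.2f ml\n", nm, x$bland_altman[[nm]]$bias))
  }
  invisible(x)
}

#' Write the study tables and plots
#'
#' Emits CSV analogues of the study's result tables (correlated groups,
#' selected indices, inter-method variability, inter-observer
#' reproducibility, Bland-Altman summaries, feature matrix, exclusion log)
#' and, optionally, one Bland-Altman PNG per method pair with a solid bias
#' line and dashed limits of agreement.
#'
#' @param report A [run_study()] report.
#' @param output_dir Output directory (created if needed).
#' @param plots Write Bland-Altman PNGs.
#' @return Character vector of written paths, invisibly.
#' @export
report_tables <- function(report, output_dir, plots = TRUE) {
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  wr <- function(df, name) {
    p <- file.path(output_dir, name)
    write.csv(df, p, row.names = FALSE)
    paths <<- c(paths, p)
  }
  if (!is.null(report$groups)) {
    wr(do.call(rbind, lapply(report$groups, function(g) data.frame(
      members = paste(g$members, collapse = ", "),
      mean_abs_r = g$mean_abs_r, sd_abs_r = g$sd_abs_r))), "groups.csv")
  }
  wr(data.frame(feature = report$selected %||% character(0)), "selected.csv")
  if (!is.null(report$variability)) wr(report$variability, "variability.csv")
  if (!is.null(report$reproducibility))
    wr(report$reproducibility, "reproducibility.csv")
  if (!is.null(report$bland_altman)) {
    wr(do.call(rbind, lapply(names(report$bland_altman), function(nm) {
      b <- report$bland_altman[[nm]]
      data.frame(pair = nm, bias = b$bias, sd_diff = b$sd_diff,
                 loa_low = b$loa_low, loa_high = b$loa_high, n = b$n)
    })), "bland_altman.csv")
  }
  wr(report$features, "features.csv")
  wr(report$exclusion_log, "exclusions.csv")
  if (plots && !is.null(report$bland_altman)) {
    for (nm in names(report$bland_altman)) {
      b <- report$bland_altman[[nm]]
      p <- file.path(output_dir, paste0("bland_altman_", nm, ".png"))
      grDevices::png(p, width = 800, height = 600)
      plot(b$mean, b$diff, pch = 19,
           xlab = "Mean MTV (ml)", ylab = "Difference (ml)",
           main = gsub("_", " ", nm))
      graphics::abline(h = b$bias, col = "blue", lwd = 2)
      graphics::abline(h = c(b$loa_low, b$loa_high), col = "red", lty = 2)
      grDevices::dev.off()
      paths <- c(paths, p)
    }
  }
  invisible(paths)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
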