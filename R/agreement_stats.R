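#' Pairwise Pearson correlation matrix of a feature table
#'
#' Pairwise-complete Pearson correlations between feature columns; flagged
#' missing values are excluded pair by pair. Zero-variance features yield
#' `NA` rows/columns and are listed in the `"flagged"` attribute.
#'
#' @param features Data frame of feature rows (e.g. from
#'   [extract_features()]).
#' @param columns Feature columns to correlate; defaults to every numeric
#'   column except provenance.
#' @return Symmetric correlation matrix with unit diagonal; attribute
#'   `"flagged"` names zero-variance columns.
#' @export
pearson_matrix <- function(features, columns = NULL) {
  if (is.null(columns)) {
    num <- vapply(features, is.numeric, logical(1))
    columns <- setdiff(names(features)[num], c("patient", "method", "observer"))
  }
  x <- as.matrix(features[columns])
  flagged <- columns[apply(x, 2, function(v) {
    v <- v[is.finite(v)]
    length(v) < 2 || sd(v) == 0
  })]
  r <- suppressWarnings(cor(x, use = "pairwise.complete.obs"))
  diag(r) <- 1
  attr(r, "flagged") <- flagged
  r
}

#' Groups of highly correlated features
#'
#' Greedy complete-linkage grouping: features are processed in the order of
#' the matrix rows; each unassigned feature opens a group, and any later
#' unassigned feature whose absolute correlation with EVERY current member
#' exceeds `threshold` joins it. Singleton groups have undefined mean/SD
#' (reported `NA`).
#'
#' @param r_matrix Square symmetric correlation matrix with named rows.
#' @param threshold Absolute-correlation threshold (default 0.8, strict).
#' @return List of groups, each `list(members, mean_abs_r, sd_abs_r)`.
#' @export
extract_correlated_groups <- function(r_matrix, threshold = 0.8) {
  feats <- rownames(r_matrix)
  stopifnot(!is.null(feats), nrow(r_matrix) == ncol(r_matrix))
  unassigned <- feats
  groups <- list()
  while (length(unassigned) > 0) {
    seed <- unassigned[1]
    members <- seed
    unassigned <- unassigned[-1]
    repeat {
      joined <- FALSE
      for (f in unassigned) {
        rr <- abs(r_matrix[f, members])
        if (all(is.finite(rr)) && all(rr > threshold)) {
          members <- c(members, f)
          unassigned <- setdiff(unassigned, f)
          joined <- TRUE
        }
      }
      if (!joined) break
    }
    if (length(members) > 1) {
      pr <- abs(r_matrix[members, members][upper.tri(diag(length(members)))])
      groups[[length(groups) + 1]] <- list(members = members,
                                           mean_abs_r = mean(pr),
                                           sd_abs_r = if (length(pr) > 1) sd(pr) else NA_real_)
    } else {
      groups[[length(groups) + 1]] <- list(members = members,
                                           mean_abs_r = NA_real_,
                                           sd_abs_r = NA_real_)
    }
  }
  groups
}

#' Select one independent index per correlation group
#'
#' Picks a representative per group (the first member in processing order
#' unless overridden), then drops representatives whose absolute correlation
#' with SUVmax or MTV exceeds `threshold`.
#'
#' @param groups Output of [extract_correlated_groups()].
#' @param r_with_standard Matrix or data frame with one row per feature and
#'   columns `SUVmax` and `MTV` holding the correlations with the standard
#'   parameters.
#' @param threshold Absolute-correlation threshold (default 0.8).
#' @param representatives Optional named character vector overriding the
#'   representative of specific groups (name = first member of the group).
#' @return Character vector of surviving feature names.
#' @export
select_independent_indices <- function(groups, r_with_standard, threshold = 0.8,
                                       representatives = NULL) {
  reps <- vapply(groups, function(g) {
    first <- g$members[1]
    if (!is.null(representatives) && first %in% names(representatives))
      representatives[[first]]
    else first
  }, character(1))
  keep <- vapply(reps, function(f) {
    if (!f %in% rownames(r_with_standard)) return(TRUE)
    rs <- abs(r_with_standard[f, c("SUVmax", "MTV")])
    rs <- rs[is.finite(rs)]
    all(rs <= threshold)
  }, logical(1))
  unname(reps[keep])
}

#' Bland-Altman agreement of two paired series
#'
#' Bias is the mean difference `a - b`; the 95% limits of agreement are
#' `bias +/- 1.96 * SD(a - b)` (SD with `n - 1`).
#'
#' @param a,b Paired numeric series of equal length (>= 2).
#' @return Object of class `bland_altman`: `bias`, `sd_diff`, `loa_low`,
#'   `loa_high`, `n`, and the per-pair `mean`/`diff` vectors for plotting.
#' @export
bland_altman <- function(a, b) {
  if (length(a) != length(b)) stop("paired series must have equal length")
  if (length(a) < 2) stop("need at least 2 pairs")
  d <- a - b
  bias <- mean(d)
  s <- sd(d)
  structure(list(bias = bias, sd_diff = s,
                 loa_low = bias - 1.96 * s, loa_high = bias + 1.96 * s,
                 n = length(d), mean = (a + b) / 2, diff = d),
            class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("<bland_altman> bias %.3f, LoA [%.3f, %.3f], n = %d\n",
              x$bias, x$loa_low, x$loa_high, x$n))
  invisible(x)
}

#' Friedman test across conditions
#'
#' Rank-based Friedman chi-square over a subjects-by-conditions matrix
#' (average ranks for ties), delegated to [stats::friedman.test()].
#'
#' @param values Numeric matrix, one row per subject, one column per
#'   condition (e.g. the three delineation methods).
#' @return List: `statistic`, `p_value`, `df`.
#' @export
friedman_test <- function(values) {
  values <- as.matrix(values)
  if (nrow(values) < 2) stop("need at least 2 subjects")
  ht <- friedman.test(values)
  stat <- unname(ht$statistic)
  p <- ht$p.value
  if (!is.finite(stat)) { stat <- 0; p <- 1 }  # every row constant: no signal
  list(statistic = stat, p_value = p, df = unname(ht$parameter))
}

#' Wilcoxon signed-rank test for paired series
#'
#' Two-sided signed-rank test on `a - b` after dropping zero differences:
#' exact null distribution up to 25 non-zero pairs, normal approximation with
#' continuity (and tie) correction beyond. All-zero differences are reported
#' as a degenerate result with `p = 1`.
#'
#' @param a,b Paired numeric series.
#' @return List: `statistic` (V), `p_value`, `n` (non-zero pairs),
#'   `degenerate`.
#' @export
wilcoxon_signed_rank <- function(a, b) {
  if (length(a) != length(b)) stop("paired series must have equal length")
  d <- a - b
  nz <- sum(d != 0)
  if (nz == 0)
    return(list(statistic = NA_real_, p_value = 1, n = 0L, degenerate = TRUE))
  ht <- suppressWarnings(wilcox.test(a, b, paired = TRUE,
                                     exact = nz <= 25, correct = TRUE))
  list(statistic = unname(ht$statistic), p_value = ht$p.value, n = nz,
       degenerate = FALSE)
}

#' Intraclass correlation, two-way random absolute agreement, single measure
#'
#' ICC(2,1) from the standard mean-squares decomposition of the two-observer
#' design: subjects are random rows, observers random columns, and systematic
#' observer offsets penalize the coefficient. Identical series give exactly
#' 1; the coefficient may be negative. When every measurement is identical
#' (no between-subject variance to resolve) the ICC is undefined and `NA` is
#' returned.
#'
#' @param obs1,obs2 Paired numeric series (length >= 3) from the two
#'   observers.
#' @return The ICC as a single number (possibly `NA`).
#' @export
icc_agreement <- function(obs1, obs2) {
  if (length(obs1) != length(obs2)) stop("series must have equal length")
  n <- length(obs1)
  if (n < 3) stop("need at least 3 subjects")
  x <- cbind(obs1, obs2)
  k <- 2
  g <- mean(x)
  rm_ <- rowMeans(x)
  cm <- colMeans(x)
  ssr <- k * sum((rm_ - g)^2)
  ssc <- n * sum((cm - g)^2)
  sst <- sum((x - g)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  denom <- msr + (k - 1) * mse + k * (msc - mse) / n
  if (abs(denom) < 1e-24) return(NA_real_)
  (msr - mse) / denom
}

#' Landis-Koch interpretation of an agreement coefficient
#'
#' Excellent above 0.8 (strictly), great in (0.6, 0.8], moderate in
#' (0.4, 0.6], low in (0.2, 0.4], poor at or below 0.2.
#'
#' @param icc ICC value (at most 1); `NA` propagates.
#' @return Character label.
#' @export
landis_koch_label <- function(icc) {
  vapply(icc, function(v) {
    if (is.na(v)) return(NA_character_)
    if (v > 1 + 1e-9) stop("ICC cannot exceed 1")
    if (v > 0.8) "excellent"
    else if (v > 0.6) "great"
    else if (v > 0.4) "moderate"
    else if (v > 0.2) "low"
    else "poor"
  }, character(1))
}
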