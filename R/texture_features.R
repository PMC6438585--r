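#' Gray-level discretization configuration
#'
#' Absolute resampling: SUVs are clamped to `[lower_bound, upper_bound]` and
#' binned into `n_levels` fixed-width levels identical for every patient. The
#' defaults (64 levels over 0-30 SUV) cover the typical tumor SUV range in
#' head-and-neck imaging.
#'
#' @param n_levels Number of gray levels (>= 2).
#' @param lower_bound,upper_bound SUV bounds of the resampling range.
#' @return Object of class `discretization_config`.
#' @export
discretization_config <- function(n_levels = 64L, lower_bound = 0,
                                  upper_bound = 30) {
  stopifnot(n_levels >= 2, upper_bound > lower_bound)
  structure(list(n_levels = as.integer(n_levels),
                 lower_bound = lower_bound, upper_bound = upper_bound),
            class = "discretization_config")
}

#' Absolute-resampled gray levels of a VOI
#'
#' Maps each masked voxel SUV `v` to level
#' `1 + floor(n_levels * (clamp(v) - lower) / (upper - lower))`, with values
#' at or above the upper bound assigned the top level. Voxels outside the
#' mask hold level 0.
#'
#' @param volume A [pet_volume()].
#' @param mask A non-empty [voi_mask()].
#' @param config A [discretization_config()].
#' @return Object of class `discretized_voi`: `levels` (3D integer array, 0
#'   outside the mask), `n_levels`, `n_voxels`, `spacing`.
#' @export
discretize_absolute <- function(volume, mask, config = discretization_config()) {
  if (mask$n_voxels == 0) stop("mask is empty")
  v <- volume$values[mask$mask]
  n <- config$n_levels
  w <- (config$upper_bound - config$lower_bound)
  lev <- 1L + as.integer(floor(n * (pmin(pmax(v, config$lower_bound),
                                         config$upper_bound) -
                                      config$lower_bound) / w))
  lev[lev > n] <- n
  levels <- array(0L, dim(mask$mask))
  levels[mask$mask] <- lev
  structure(list(levels = levels, n_levels = n, n_voxels = mask$n_voxels,
                 spacing = mask$spacing),
            class = "discretized_voi")
}

## Crop the level array to the mask bounding box (keeps builders fast).
crop_levels <- function(dvoi) {
  bb <- bbox_of(dvoi$levels > 0L)
  dvoi$levels[bb$x, bb$y, bb$z, drop = FALSE]
}

#' Gray-level co-occurrence matrix
#'
#' Counts of level pairs at Chebyshev distance 1, accumulated over all 26
#' ordered voxel offsets (13 directions, both signs) into a single symmetric
#' matrix; both pair endpoints must lie in the VOI.
#'
#' @param dvoi A [discretize_absolute()] result.
#' @return List: `counts` (`n_levels x n_levels`), `p` (normalized copy
#'   summing to 1), `n_pairs`, `degenerate` (TRUE when no valid pair exists).
#' @export
build_glcm <- function(dvoi) {
  lev <- crop_levels(dvoi)
  n <- dvoi$n_levels
  counts <- matrix(0, n, n)
  for (d in offsets_13()) {
    b <- shift3(lev, -d, fill = 0L)      # b[i] = lev at i + d
    keep <- lev > 0L & b > 0L
    if (!any(keep)) next
    i <- lev[keep]; j <- b[keep]
    tab <- tabulate((j - 1L) * n + i, nbins = n * n)
    m <- matrix(tab, n, n)
    counts <- counts + m + t(m)          # both signs of the offset
  }
  tot <- sum(counts)
  list(counts = counts,
       p = if (tot > 0) counts / tot else counts,
       n_pairs = tot / 2,
       degenerate = tot == 0)
}

#' Co-occurrence indices
#'
#' Homogeneity, Energy, Contrast_glcm, Correlation, Entropy (log base 2) and
#' Dissimilarity of a normalized co-occurrence matrix. Correlation is a
#' flagged missing value (`NA`) when the marginal variance is zero (constant
#' VOI).
#'
#' @param glcm A [build_glcm()] result.
#' @return Named numeric vector of the 6 indices.
#' @export
glcm_indices <- function(glcm) {
  p <- glcm$p
  n <- nrow(p)
  i <- row(p); j <- col(p)
  adiff <- abs(i - j)
  homog <- sum(p / (1 + adiff))
  energy <- sum(p^2)
  contrast <- sum((i - j)^2 * p)
  dissim <- sum(adiff * p)
  nz <- p > 0
  entropy <- -sum(p[nz] * log2(p[nz]))
  pm <- rowSums(p)                       # marginals equal by symmetry
  mu <- sum(seq_len(n) * pm)
  s2 <- sum((seq_len(n) - mu)^2 * pm)
  corr <- if (s2 > 1e-12) (sum(i * j * p) - mu^2) / s2 else NA_real_
  c(Homogeneity = homog, Energy = energy, Contrast_glcm = contrast,
    Correlation = corr, Entropy = entropy, Dissimilarity = dissim)
}

#' Gray-level run-length matrix
#'
#' Maximal runs of equal-level collinear voxels inside the VOI, accumulated
#' over the 13 lattice directions into one `n_levels x max-run` count matrix.
#'
#' @param dvoi A [discretize_absolute()] result.
#' @return Integer matrix of run counts (rows = levels, cols = run lengths).
#' @export
build_glrlm <- function(dvoi) {
  lev <- crop_levels(dvoi)
  d <- dim(lev)
  w <- which(lev > 0L, arr.ind = TRUE)
  lv <- lev[lev > 0L]
  runs <- list()
  for (dd in offsets_13()) {
    ## a lattice line with step dd is identified by the cross product of the
    ## voxel coordinate with dd; position along the line is the dot product,
    ## which advances by |dd|^2 between consecutive line voxels.
    k1 <- w[, 2] * dd[3] - w[, 3] * dd[2]
    k2 <- w[, 3] * dd[1] - w[, 1] * dd[3]
    k3 <- w[, 1] * dd[2] - w[, 2] * dd[1]
    pos <- w[, 1] * dd[1] + w[, 2] * dd[2] + w[, 3] * dd[3]
    stepsq <- sum(dd^2)
    ord <- order(k1, k2, k3, pos)
    lvo <- lv[ord]
    poso <- pos[ord]
    newline <- c(TRUE, diff(k1[ord]) != 0 | diff(k2[ord]) != 0 |
                   diff(k3[ord]) != 0)
    gap <- c(TRUE, diff(poso) != stepsq)
    brk <- newline | gap
    newrun <- brk | c(TRUE, lvo[-1] != lvo[-length(lvo)])
    rid <- cumsum(newrun)
    rl <- tabulate(rid)
    rlev <- lvo[newrun]
    runs[[length(runs) + 1]] <- cbind(rlev, rl)
  }
  allr <- do.call(rbind, runs)
  lmax <- max(allr[, 2])
  mat <- matrix(0L, dvoi$n_levels, lmax)
  tab <- tabulate((allr[, 2] - 1L) * dvoi$n_levels + allr[, 1],
                  nbins = dvoi$n_levels * lmax)
  mat[] <- tab
  mat
}

## Shared emphasis formulas of the run-length and zone-length families.
rl_family_indices <- function(mat, n_voxels, rp_denom, prefix_zone = FALSE) {
  N <- sum(mat)
  iv <- seq_len(nrow(mat))
  lv <- seq_len(ncol(mat))
  ri <- rowSums(mat)
  rl <- colSums(mat)
  i2 <- iv^2
  l2 <- lv^2
  sre <- sum(rl / l2) / N
  lre <- sum(rl * l2) / N
  lgre <- sum(ri / i2) / N
  hgre <- sum(ri * i2) / N
  srlge <- sum(outer(1 / i2, 1 / l2) * mat) / N
  srhge <- sum(outer(i2, 1 / l2) * mat) / N
  lrlge <- sum(outer(1 / i2, l2) * mat) / N
  lrhge <- sum(outer(i2, l2) * mat) / N
  glnu <- sum(ri^2) / N
  rlnu <- sum(rl^2) / N
  rp <- N / rp_denom
  v <- c(sre, lre, lgre, hgre, srlge, srhge, lrlge, lrhge, glnu, rlnu, rp)
  names(v) <- if (prefix_zone)
    c("SZE", "LZE", "LGZE", "HGZE", "SZLGE", "SZHGE", "LZLGE", "LZHGE",
      "GLNUz", "ZLNU", "ZP")
  else
    c("SRE", "LRE", "LGRE", "HGRE", "SRLGE", "SRHGE", "LRLGE", "LRHGE",
      "GLNUr", "RLNU", "RP")
  v
}

#' Run-length indices
#'
#' The 11 standard run-length emphases of the direction-aggregated matrix;
#' Run Percentage uses `13 * n_voxels` as denominator so it stays in `(0, 1]`.
#'
#' @param glrlm A [build_glrlm()] matrix.
#' @param n_voxels Number of voxels in the VOI.
#' @param n_directions Number of aggregated directions (13).
#' @return Named numeric vector of the 11 indices.
#' @export
glrlm_indices <- function(glrlm, n_voxels, n_directions = 13) {
  rl_family_indices(glrlm, n_voxels, rp_denom = n_directions * n_voxels)
}

#' Neighborhood gray-level dependence matrix
#'
#' For every VOI voxel the dependence is the number of its in-mask
#' 26-neighbors with exactly the same level (edge voxels simply have fewer
#' neighbors). `Q[i, k+1]` counts voxels of level `i` with dependence `k`.
#' The coarseness/contrast/busyness indices additionally use the
#' per-level totals of the absolute difference between a voxel's level and
#' the mean level of its in-mask neighbors.
#'
#' @param dvoi A [discretize_absolute()] result.
#' @return List: `Q` (`n_levels x 27` dependence counts), `s_i` (per-level
#'   absolute-difference totals), `n_i` (per-level voxel counts), `n_voxels`.
#' @export
build_ngldm <- function(dvoi) {
  lev <- crop_levels(dvoi)
  inmask <- lev > 0L
  dep <- array(0L, dim(lev))
  nsum <- array(0, dim(lev))
  ncnt <- array(0L, dim(lev))
  for (d in neighbor_offsets_26()) {
    nb <- shift3(lev, -d, fill = 0L)
    has <- inmask & nb > 0L
    dep <- dep + (has & nb == lev)
    nsum <- nsum + ifelse(has, nb, 0)
    ncnt <- ncnt + has
  }
  lv <- lev[inmask]
  dp <- dep[inmask]
  n <- dvoi$n_levels
  Q <- matrix(0L, n, 27L)
  tab <- tabulate(dp * n + lv, nbins = 27L * n)
  Q[] <- tab
  avg <- ifelse(ncnt[inmask] > 0, nsum[inmask] / ncnt[inmask], lv)
  adiff <- abs(lv - avg)
  s_i <- vapply(seq_len(n), function(i) sum(adiff[lv == i]), numeric(1))
  n_i <- tabulate(lv, nbins = n)
  list(Q = Q, s_i = s_i, n_i = n_i, n_voxels = length(lv))
}

#' Neighborhood dependence indices
#'
#' Coarseness, Contrast and Busyness in the Amadasun-King normalization over
#' the per-level difference totals of [build_ngldm()]. Coarseness is guarded
#' with a small epsilon so perfectly uniform VOIs stay finite; Busyness is a
#' flagged missing value (`NA`) when its denominator vanishes (constant VOI).
#'
#' @param ngldm A [build_ngldm()] result.
#' @return Named numeric vector `c(Coarseness, Contrast, Busyness)`.
#' @export
ngldm_indices <- function(ngldm) {
  N <- ngldm$n_voxels
  present <- which(ngldm$n_i > 0)
  p_i <- ngldm$n_i / N
  s_i <- ngldm$s_i
  coarse <- 1 / (sum(p_i * s_i) + 1e-6)
  np <- length(present)
  contrast <- if (np >= 2) {
    pp <- p_i[present]
    ii <- present
    sum(outer(pp, pp) * outer(ii, ii, function(a, b) (a - b)^2)) /
      (np * (np - 1)) * sum(s_i) / N
  } else 0
  denom <- if (np >= 2) {
    ip <- present * p_i[present]
    sum(abs(outer(ip, ip, "-")))
  } else 0
  busy <- if (denom > 1e-12) sum(p_i * s_i) / denom else NA_real_
  c(Coarseness = coarse, Contrast = contrast, Busyness = busy)
}

#' Gray-level zone-length matrix
#'
#' Zones are 26-connected components of equal-level voxels within the VOI;
#' `Z[i, s]` counts zones of level `i` and size `s` voxels.
#'
#' @param dvoi A [discretize_absolute()] result.
#' @return Integer matrix of zone counts (rows = levels, cols = zone sizes).
#' @export
build_glzlm <- function(dvoi) {
  lev <- crop_levels(dvoi)
  lab <- .label26(lev, as.integer(dim(lev)), TRUE)
  nz <- max(lab)
  sizes <- tabulate(lab[lab > 0L], nbins = nz)
  zlev <- integer(nz)
  flat_lab <- as.integer(lab)
  flat_lev <- as.integer(lev)
  first <- match(seq_len(nz), flat_lab)
  zlev <- flat_lev[first]
  smax <- max(sizes)
  mat <- matrix(0L, dvoi$n_levels, smax)
  tab <- tabulate((sizes - 1L) * dvoi$n_levels + zlev,
                  nbins = dvoi$n_levels * smax)
  mat[] <- tab
  mat
}

#' Zone-length indices
#'
#' Same functional forms as [glrlm_indices()] with runs replaced by zones;
#' Zone Percentage is the number of zones over the number of voxels.
#'
#' @param glzlm A [build_glzlm()] matrix.
#' @param n_voxels Number of voxels in the VOI.
#' @return Named numeric vector of the 11 indices.
#' @export
glzlm_indices <- function(glzlm, n_voxels) {
  rl_family_indices(glzlm, n_voxels, rp_denom = n_voxels, prefix_zone = TRUE)
}

#' Canonical texture index names
#'
#' The 31 texture indices in inventory order (6 co-occurrence, 11 run-length,
#' 3 neighborhood-dependence, 11 zone-length). This order also fixes the
#' processing order of the correlation grouping.
#'
#' @return Character vector of length 31.
#' @export
texture_feature_names <- function() {
  c("Homogeneity", "Energy", "Contrast_glcm", "Correlation", "Entropy",
    "Dissimilarity",
    "SRE", "LRE", "LGRE", "HGRE", "SRLGE", "SRHGE", "LRLGE", "LRHGE",
    "GLNUr", "RLNU", "RP",
    "Coarseness", "Contrast", "Busyness",
    "SZE", "LZE", "LGZE", "HGZE", "SZLGE", "SZHGE", "LZLGE", "LZHGE",
    "GLNUz", "ZLNU", "ZP")
}

#' Extract the full feature vector of a VOI
#'
#' Runs the absolute discretization, the four matrix builders and their index
#' sets, plus SUVmax and MTV. The VOI must be a single 26-connected component
#' of at least `min_voxels` voxels (the analyzability floor); smaller VOIs
#' raise an ineligibility error. `Correlation` and `Busyness` may be flagged
#' missing (`NA`) on degenerate (constant) VOIs; all other fields are finite.
#'
#' @param volume A [pet_volume()].
#' @param mask A [voi_mask()].
#' @param disc_config A [discretization_config()].
#' @param patient,method,observer Provenance columns of the returned row;
#'   `method`/`observer` default to the mask's tags.
#' @param min_voxels Analyzability floor (64).
#' @return One-row `data.frame`: `patient`, `method`, `observer`, `SUVmax`,
#'   `MTV`, then the 31 texture indices of [texture_feature_names()].
#' @export
extract_features <- function(volume, mask, disc_config = discretization_config(),
                             patient = "P01", method = NULL, observer = NULL,
                             min_voxels = 64L) {
  elig <- check_min_volume(mask, min_voxels)
  if (!elig$eligible)
    stop("VOI ineligible for texture analysis: ", mask$n_voxels,
         " voxels < ", min_voxels)
  lab <- label_components(mask$mask)
  if (max(lab) > 1)
    stop("VOI must be a single 26-connected component")
  dv <- discretize_absolute(volume, mask, disc_config)
  glcm <- glcm_indices(build_glcm(dv))
  glrlm <- glrlm_indices(build_glrlm(dv), dv$n_voxels)
  ngldm <- ngldm_indices(build_ngldm(dv))
  glzlm <- glzlm_indices(build_glzlm(dv), dv$n_voxels)
  vals <- c(glcm, glrlm, ngldm, glzlm)
  stopifnot(identical(names(vals), texture_feature_names()))
  out <- data.frame(patient = patient,
                    method = if (is.null(method)) mask$method else method,
                    observer = if (is.null(observer)) mask$observer else observer,
                    SUVmax = compute_suvmax(volume, mask),
                    MTV = compute_mtv(mask),
                    stringsAsFactors = FALSE)
  out[names(vals)] <- as.list(unname(vals))
  out
}
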