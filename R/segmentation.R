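#' Segmentation configuration
#'
#' Parameters shared by the three delineation methods. The search region is a
#' sphere of `search_radius_mm` around the observer's seed point; it stands in
#' for the reader's implicit restriction to the tumor neighborhood and is the
#' vehicle of observer dependence.
#'
#' @param fixed_threshold_fraction Fraction of the regional SUVmax used by the
#'   fixed-threshold method (default 0.40; comparison is inclusive, `>=`).
#' @param background_shell_mm Thickness (mm) of the background shell used by
#'   [estimate_sbr()].
#' @param guard_mm Guard margin (mm) between the mask and the background
#'   shell, excluding spill-over voxels from the background estimate.
#' @param adaptive_coeffs Numeric `c(a, b)` of the adaptive threshold law
#'   `t = a / SBR + b`, from [calibrate_adaptive_thresholds()]; `NULL` until
#'   calibrated.
#' @param gradient_sigma_mm Gaussian smoothing scale (mm) applied before
#'   gradient computation.
#' @param n_rays Number of radial directions for edge detection (>= 26).
#' @param search_radius_mm Radius (mm) of the search sphere around the seed.
#' @param max_iter Iteration cap of the adaptive fixed point.
#' @return Object of class `segmentation_config`.
#' @export
segmentation_config <- function(fixed_threshold_fraction = 0.40,
                                background_shell_mm = 10,
                                guard_mm = 4,
                                adaptive_coeffs = NULL,
                                gradient_sigma_mm = 2,
                                n_rays = 256L,
                                search_radius_mm = 60,
                                max_iter = 10L) {
  stopifnot(fixed_threshold_fraction > 0, fixed_threshold_fraction < 1,
            n_rays >= 26, background_shell_mm > 0, guard_mm >= 0,
            gradient_sigma_mm >= 0, search_radius_mm > 0, max_iter >= 1)
  if (!is.null(adaptive_coeffs)) stopifnot(length(adaptive_coeffs) == 2)
  structure(
    list(fixed_threshold_fraction = fixed_threshold_fraction,
         background_shell_mm = background_shell_mm,
         guard_mm = guard_mm,
         adaptive_coeffs = adaptive_coeffs,
         gradient_sigma_mm = gradient_sigma_mm,
         n_rays = as.integer(n_rays),
         search_radius_mm = search_radius_mm,
         max_iter = as.integer(max_iter)),
    class = "segmentation_config")
}

## 26-connected component labels of a logical array (Rcpp flood fill).
label_components <- function(mask) {
  .label26(array(as.integer(mask), dim(mask)), as.integer(dim(mask)), FALSE)
}

#' Keep the most representative cluster of a mask
#'
#' Labels the 26-connected components of the mask and keeps the component
#' containing the global maximum-SUV voxel of the mask; if that maximum is
#' tied across components, the largest component wins, with a residual tie
#' broken by lowest component label. This is a deterministic reading of an
#' operator choosing the cluster by uptake intensity and volume.
#'
#' @param mask A [voi_mask()] (or logical array with `volume` geometry).
#' @param volume The aligned [pet_volume()].
#' @return A [voi_mask()] that is a single 26-connected component.
#' @export
select_representative_cluster <- function(mask, volume) {
  arr <- if (inherits(mask, "voi_mask")) mask$mask else mask
  if (!any(arr)) stop("mask is empty")
  lab <- label_components(arr)
  keep <- representative_label(lab, volume$values, arr)
  out <- lab == keep
  if (inherits(mask, "voi_mask"))
    voi_mask(out, volume, method = mask$method, observer = mask$observer)
  else out
}

representative_label <- function(lab, values, arr) {
  vmax <- max(values[arr])
  cand <- sort(unique(lab[arr & values == vmax]))
  if (length(cand) > 1) {
    sizes <- vapply(cand, function(l) sum(lab == l), integer(1))
    cand <- cand[sizes == max(sizes)]
  }
  cand[1]
}

## Shared precondition checks + search region for the threshold methods.
search_region <- function(volume, seed_point, config) {
  d <- dim(volume$values)
  seed_point <- round(seed_point)
  if (any(seed_point < 1) || any(seed_point > d))
    stop("seed point outside the grid")
  region <- sphere_region(d, seed_point, config$search_radius_mm,
                          volume$spacing)
  if (max(volume$values[region]) <= 0)
    stop("search region contains no positive uptake")
  region
}

#' Fixed-threshold delineation (40% SUVmax)
#'
#' Includes every voxel of the search region with SUV greater than or equal
#' to `fixed_threshold_fraction` times the regional SUVmax, then keeps the
#' most representative 26-connected cluster.
#'
#' @param volume A [pet_volume()].
#' @param seed_point Observer seed click, voxel coordinates.
#' @param config A [segmentation_config()].
#' @param observer Observer tag recorded on the mask.
#' @return A [voi_mask()] with method `"FIXED40"`.
#' @export
segment_fixed_threshold <- function(volume, seed_point, config = segmentation_config(),
                                    observer = "obs1") {
  region <- search_region(volume, seed_point, config)
  thr <- config$fixed_threshold_fraction * max(volume$values[region])
  arr <- region & volume$values >= thr
  m <- voi_mask(arr, volume, method = "FIXED40", observer = observer)
  select_representative_cluster(m, volume)
}

#' Signal-to-background ratio of a provisional mask
#'
#' `suv_max` is the maximum SUV inside the mask; `background_mean` the mean
#' SUV in a shell obtained by excluding a guard margin around the mask and
#' keeping voxels within `background_shell_mm` beyond it.
#'
#' @param volume A [pet_volume()].
#' @param provisional_mask A non-empty [voi_mask()].
#' @param config A [segmentation_config()].
#' @return Object of class `sbr_estimate`: `suv_max`, `background_mean`,
#'   `sbr`.
#' @export
estimate_sbr <- function(volume, provisional_mask, config = segmentation_config()) {
  arr <- provisional_mask$mask
  if (!any(arr)) stop("provisional mask is empty")
  shell <- distance_shell(arr, volume$spacing, config$guard_mm,
                          config$background_shell_mm)
  if (!any(shell)) stop("background shell is empty")
  bg <- mean(volume$values[shell])
  if (bg <= 0) stop("background mean is zero; SBR undefined")
  smax <- max(volume$values[arr])
  structure(list(suv_max = smax, background_mean = bg, sbr = smax / bg),
            class = "sbr_estimate")
}

#' Adaptive signal-to-background threshold delineation
#'
#' Starts from the 40% SUVmax provisional mask and iterates to a fixed point:
#' estimate the SBR of the current mask, map it to a threshold fraction
#' `t = a / SBR + b` (clamped to `[0.2, 0.8]`), re-threshold and re-select the
#' representative cluster. The fraction applies to the mean uptake of the
#' current mask — a reference robust to focal hot spots — so that on
#' heterogeneous lesions the method reaches below the fixed 40% SUVmax cut,
#' as adaptive methods do in practice. `(a, b)` come from
#' [calibrate_adaptive_thresholds()].
#'
#' @inheritParams segment_fixed_threshold
#' @return A [voi_mask()] with method `"ADAPTIVE_SBR"`; attribute
#'   `"converged"` records whether the fixed point was reached within
#'   `config$max_iter` iterations.
#' @export
segment_adaptive_sbr <- function(volume, seed_point, config = segmentation_config(),
                                 observer = "obs1") {
  if (is.null(config$adaptive_coeffs))
    stop("adaptive_coeffs not set; run calibrate_adaptive_thresholds() first")
  a <- config$adaptive_coeffs[1]; b <- config$adaptive_coeffs[2]
  region <- search_region(volume, seed_point, config)
  mask <- segment_fixed_threshold(volume, seed_point, config, observer)
  prev <- NULL
  converged <- FALSE
  for (it in seq_len(config$max_iter)) {
    est <- estimate_sbr(volume, mask, config)
    t <- min(max(a / est$sbr + b, 0.2), 0.8)
    thr <- t * mean(volume$values[mask$mask])
    arr <- region & volume$values >= thr
    if (!any(arr)) break  # degenerate: keep last mask
    nxt <- select_representative_cluster(
      voi_mask(arr, volume, method = "ADAPTIVE_SBR", observer = observer),
      volume)
    if (identical(nxt$mask, mask$mask)) { mask <- nxt; converged <- TRUE; break }
    if (!is.null(prev) && identical(nxt$mask, prev)) { mask <- nxt; converged <- TRUE; break }
    prev <- mask$mask
    mask <- nxt
  }
  mask <- voi_mask(mask$mask, volume, method = "ADAPTIVE_SBR",
                   observer = observer)
  attr(mask, "converged") <- converged
  if (!converged) warning("adaptive threshold did not converge; returning last mask")
  mask
}

## Fixed point of mean-referenced thresholding at a fixed fraction t,
## starting from the 40% provisional mask. Used by the calibration.
adaptive_fixed_point_volume <- function(volume, seed_point, config, t) {
  region <- search_region(volume, seed_point, config)
  mask <- segment_fixed_threshold(volume, seed_point, config)
  prev <- NULL
  for (it in seq_len(config$max_iter)) {
    thr <- t * mean(volume$values[mask$mask])
    arr <- region & volume$values >= thr
    if (!any(arr)) break
    nxt <- select_representative_cluster(
      voi_mask(arr, volume, method = "ADAPTIVE_SBR"), volume)
    if (identical(nxt$mask, mask$mask)) { mask <- nxt; break }
    if (!is.null(prev) && identical(nxt$mask, prev)) { mask <- nxt; break }
    prev <- mask$mask
    mask <- nxt
  }
  mask$volume_ml
}

#' Calibrate the adaptive threshold law on sphere phantoms
#'
#' For every combination of sphere volume and signal-to-background ratio a
#' noiseless blurred uniform sphere phantom is generated; the threshold
#' fraction whose fixed point recovers the true sphere volume is found by
#' bisection, and the fractions are fitted against `1 / SBR` by least squares,
#' yielding the coefficients `(a, b)` of `t = a / SBR + b`. The SBR entering
#' the fit is measured on the phantom exactly as the segmentation will
#' measure it.
#'
#' @param sphere_volumes_ml Sphere volumes (ml) of the calibration grid.
#' @param sbr_values Signal-to-background ratios of the calibration grid.
#' @param blur_fwhm_mm Gaussian blur FWHM (mm) of the calibration phantoms;
#'   should match the images the law will be applied to.
#' @param base_spec Template [phantom_spec()] providing grid and spacing.
#' @param config A [segmentation_config()].
#' @return Numeric `c(a, b)`; attribute `"calibration"` holds the per-phantom
#'   table (volume, measured SBR, optimal fraction, residual).
#' @export
calibrate_adaptive_thresholds <- function(sphere_volumes_ml = c(8, 15, 25, 40),
                                          sbr_values = c(4, 8, 16, 32),
                                          blur_fwhm_mm = 6,
                                          base_spec = phantom_spec(),
                                          config = segmentation_config()) {
  grid <- expand.grid(vol = sphere_volumes_ml, sbr = sbr_values)
  if (nrow(grid) < 4) stop("need at least 4 (volume, SBR) combinations")
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    spec <- base_spec
    spec$tumor_radii_mm <- radii_for_volume(grid$vol[i], ratios = c(1, 1, 1))
    spec$target_sbr <- grid$sbr[i]
    spec$suv_peak <- grid$sbr[i] * spec$background_suv
    spec$heterogeneity_amp <- 0
    spec$necrotic_fraction <- 0
    spec$noise_sd <- 0
    spec$blur_fwhm_mm <- blur_fwhm_mm
    vol <- generate_phantom(spec)
    seed_point <- round(spec$tumor_center)
    target <- attr(vol, "true_volume_ml")
    f <- function(t) adaptive_fixed_point_volume(vol, seed_point, config, t) - target
    lo <- 0.2; hi <- 0.9
    if (f(lo) < 0 || f(hi) > 0) {
      t_opt <- if (f(lo) < 0) lo else hi  # target outside bracket: clamp
    } else {
      for (k in 1:18) {
        mid <- (lo + hi) / 2
        if (f(mid) >= 0) lo <- mid else hi <- mid
      }
      t_opt <- (lo + hi) / 2
    }
    prov <- segment_fixed_threshold(vol, seed_point, config)
    sbr_meas <- estimate_sbr(vol, prov, config)$sbr
    data.frame(volume_ml = grid$vol[i], sbr_nominal = grid$sbr[i],
               sbr_measured = sbr_meas, fraction = t_opt)
  })
  cal <- do.call(rbind, rows)
  if (length(unique(grid$sbr)) < 2 || sd(1 / cal$sbr_measured) < 1e-9) {
    coeffs <- c(a = 0, b = mean(cal$fraction))
    cal$residual <- cal$fraction - mean(cal$fraction)
  } else {
    fit <- lm(fraction ~ I(1 / sbr_measured), data = cal)
    coeffs <- c(a = unname(coef(fit)[2]), b = unname(coef(fit)[1]))
    cal$residual <- unname(residuals(fit))
  }
  attr(coeffs, "calibration") <- cal
  coeffs
}

#' Gradient-edge delineation
#'
#' Smooths the volume, casts quasi-uniform rays from the search region's
#' maximum-uptake voxel, and places the boundary on each ray at the maximum
#' magnitude of the falling radial derivative. The boundary radii are
#' interpolated over directions, the interior voxelized, closed
#' morphologically and reduced to the representative cluster. The ray lattice
#' is oriented along the seed-to-center axis, so the click position (the
#' observer) influences the reconstructed surface as it does in interactive
#' gradient tools.
#'
#' @inheritParams segment_fixed_threshold
#' @param max_failed_fraction Error threshold on the fraction of rays without
#'   a falling-gradient extremum.
#' @return A [voi_mask()] with method `"GRADIENT_EDGE"`.
#' @export
segment_gradient_edge <- function(volume, seed_point, config = segmentation_config(),
                                  observer = "obs1", max_failed_fraction = 0.2) {
  region <- search_region(volume, seed_point, config)
  d <- dim(volume$values)
  sp <- volume$spacing
  sm <- if (config$gradient_sigma_mm > 0)
    gaussian_smooth(volume$values, config$gradient_sigma_mm, sp)
  else volume$values
  vals <- volume$values
  vals[!region] <- -Inf
  center <- which(vals == max(vals), arr.ind = TRUE)[1, ]
  axis <- (round(seed_point) - center) * sp
  dirs <- fib_sphere_dirs(config$n_rays,
                          axis = if (sqrt(sum(axis^2)) > 1e-9) axis else NULL)
  step <- 0.5
  r <- seq(step, config$search_radius_mm, by = step)
  nr <- length(r)
  ## sample the smoothed image along every ray (voxel coordinates)
  pts <- matrix(0, nr * config$n_rays, 3)
  for (ax in 1:3)
    pts[, ax] <- center[ax] + as.vector(outer(r, dirs[, ax])) / sp[ax]
  prof <- matrix(trilinear(sm, pts), nr, config$n_rays)
  deriv <- diff(prof) / step                     # at midpoints r + step/2
  rmin <- max(sp) / 2                            # skip the immediate center
  use <- (r[-1] - step / 2) >= rmin
  rmid <- (r[-1] - step / 2)[use]
  dmat <- deriv[use, , drop = FALSE]
  boundary <- rep(NA_real_, config$n_rays)
  ## boundary = outermost strong falling edge: the farthest local minimum of
  ## the radial derivative with at least half the strength of the strongest
  ## drop (robust to intratumoral texture gradients inside the rim)
  nr2 <- nrow(dmat)
  for (q in seq_len(config$n_rays)) {
    dv <- dmat[, q]
    gmin <- min(dv)
    if (gmin >= -1e-8) next
    locmin <- which(dv <= c(dv[-1], Inf) & dv <= c(Inf, dv[-nr2]) &
                      dv <= 0.5 * gmin)
    boundary[q] <- rmid[max(locmin)]
  }
  ok <- !is.na(boundary)
  if (mean(!ok) > max_failed_fraction)
    stop("no gradient extremum on more than ",
         round(100 * max_failed_fraction), "% of rays")
  boundary[!ok] <- stats::median(boundary[ok])
  ## voxelize the interior of the interpolated boundary surface
  pad <- ceiling(max(boundary) / min(sp)) + 2L
  lo <- pmax(center - pad, 1L)
  hi <- pmin(center + pad, d)
  gx <- lo[1]:hi[1]; gy <- lo[2]:hi[2]; gz <- lo[3]:hi[3]
  g <- expand.grid(x = gx, y = gy, z = gz)
  off <- cbind((g$x - center[1]) * sp[1], (g$y - center[2]) * sp[2],
               (g$z - center[3]) * sp[3])
  rad <- sqrt(rowSums(off^2))
  vdir <- off / pmax(rad, 1e-9)
  ## inverse-angular-distance interpolation over the 3 nearest rays
  dots <- vdir %*% t(dirs)
  rb <- numeric(nrow(dots))
  wsum <- numeric(nrow(dots))
  for (k in 1:3) {
    j <- max.col(dots, ties.method = "first")
    dj <- dots[cbind(seq_len(nrow(dots)), j)]
    w <- 1 / (acos(pmin(pmax(dj, -1), 1)) + 1e-3)
    rb <- rb + w * boundary[j]
    wsum <- wsum + w
    dots[cbind(seq_len(nrow(dots)), j)] <- -Inf
  }
  rb <- rb / wsum
  inside <- rad <= rb
  sub <- array(FALSE, c(length(gx), length(gy), length(gz)))
  sub[cbind(match(g$x, gx), match(g$y, gy), match(g$z, gz))] <- inside
  sub <- erode26(dilate26(sub))                  # morphological closing
  arr <- array(FALSE, d)
  arr[gx, gy, gz] <- sub
  arr[center[1], center[2], center[3]] <- TRUE
  arr <- arr & region
  m <- voi_mask(arr, volume, method = "GRADIENT_EDGE", observer = observer)
  select_representative_cluster(m, volume)
}

#' Maximum SUV within a VOI
#'
#' @param volume A [pet_volume()].
#' @param mask A non-empty [voi_mask()].
#' @return SUVmax over the masked voxels.
#' @export
compute_suvmax <- function(volume, mask) {
  if (mask$n_voxels == 0) stop("mask is empty")
  max(volume$values[mask$mask])
}

#' Metabolic tumor volume of a VOI
#'
#' @param mask A [voi_mask()].
#' @return Volume in ml (`n_voxels` times the voxel volume).
#' @export
compute_mtv <- function(mask) mask$volume_ml

#' Run one of the three delineation methods by name
#'
#' @inheritParams segment_fixed_threshold
#' @param method One of [segmentation_methods()].
#' @return A [voi_mask()].
#' @export
segment <- function(volume, seed_point, method, config = segmentation_config(),
                    observer = "obs1") {
  method <- match.arg(method, SEGMENTATION_METHODS)
  switch(method,
    FIXED40 = segment_fixed_threshold(volume, seed_point, config, observer),
    ADAPTIVE_SBR = segment_adaptive_sbr(volume, seed_point, config, observer),
    GRADIENT_EDGE = segment_gradient_edge(volume, seed_point, config, observer))
}
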