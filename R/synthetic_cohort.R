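#' Specification of a synthetic PET phantom
#'
#' Describes one simulated lesion: an ellipsoidal tumor of textured uptake
#' embedded in a low-uptake background plateau, degraded by Gaussian
#' partial-volume blur and additive noise. The defaults emulate a
#' head-and-neck FDG acquisition: 4.07 x 4.07 x 2 mm voxels, a
#' signal-to-background ratio around 23.5, and a total image resolution of
#' about 6 mm FWHM.
#'
#' `suv_peak` is the target measured peak uptake of the lesion: the textured
#' uptake field is normalized so its maximum equals `suv_peak`, and after
#' partial-volume blurring the lesion excess over background is rescaled so
#' the post-blur peak again equals `suv_peak` — a clinical
#' signal-to-background ratio is read off the reconstructed image, so this is
#' the quantity the simulation must hit. When `suv_peak` is `NULL` it is
#' derived as `target_sbr * background_suv`.
#'
#' @param grid_shape Integer length-3 grid dimensions.
#' @param spacing Voxel spacing (mm).
#' @param tumor_center Voxel coordinates of the tumor center (defaults to the
#'   grid center).
#' @param tumor_radii_mm Ellipsoid semi-axes in mm (see [radii_for_volume()]).
#' @param suv_peak Target peak SUV before blur, or `NULL` to derive from
#'   `target_sbr`.
#' @param background_suv Background plateau SUV.
#' @param target_sbr Target signal-to-background ratio.
#' @param heterogeneity_amp Relative amplitude in `[0, 1]` of the textured
#'   (Gaussian random field) component of intratumoral uptake.
#' @param texture_corr_len_mm Correlation length (Gaussian sigma, mm) of the
#'   texture field.
#' @param necrotic_fraction Fraction in `[0, 1)` of the tumor radii occupied
#'   by a low-uptake core.
#' @param blur_fwhm_mm FWHM (mm) of the Gaussian partial-volume blur; 0
#'   disables blurring.
#' @param noise_sd SD (SUV) of additive Gaussian noise; 0 disables noise.
#' @param seed RNG seed; generation is deterministic given the spec.
#' @return Object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(36, 36, 56),
                         spacing = c(4.07, 4.07, 2),
                         tumor_center = NULL,
                         tumor_radii_mm = radii_for_volume(20),
                         suv_peak = NULL,
                         background_suv = 1.0,
                         target_sbr = 23.5,
                         heterogeneity_amp = 0.6,
                         texture_corr_len_mm = 8,
                         necrotic_fraction = 0,
                         blur_fwhm_mm = 6,
                         noise_sd = 0.15,
                         seed = 1L) {
  grid_shape <- as.integer(grid_shape)
  if (is.null(tumor_center)) tumor_center <- ceiling(grid_shape / 2)
  if (is.null(suv_peak)) suv_peak <- target_sbr * background_suv
  spec <- structure(
    list(grid_shape = grid_shape, spacing = as.numeric(spacing),
         tumor_center = as.numeric(tumor_center),
         tumor_radii_mm = as.numeric(tumor_radii_mm),
         suv_peak = suv_peak, background_suv = background_suv,
         target_sbr = target_sbr,
         heterogeneity_amp = heterogeneity_amp,
         texture_corr_len_mm = texture_corr_len_mm,
         necrotic_fraction = necrotic_fraction,
         blur_fwhm_mm = blur_fwhm_mm, noise_sd = noise_sd,
         seed = as.integer(seed)),
    class = "phantom_spec")
  validate_phantom_spec(spec)
  spec
}

validate_phantom_spec <- function(spec) {
  stopifnot(length(spec$grid_shape) == 3, all(spec$grid_shape >= 4))
  if (any(spec$spacing <= 0)) stop("spacing must be strictly positive")
  if (length(spec$tumor_radii_mm) != 3 || any(spec$tumor_radii_mm <= 0))
    stop("tumor_radii_mm must be 3 positive semi-axes")
  if (!(spec$suv_peak > spec$background_suv) || spec$background_suv <= 0)
    stop("need suv_peak > background_suv > 0")
  if (spec$heterogeneity_amp < 0 || spec$heterogeneity_amp > 1)
    stop("heterogeneity_amp must be in [0, 1]")
  if (spec$necrotic_fraction < 0 || spec$necrotic_fraction >= 1)
    stop("necrotic_fraction must be in [0, 1)")
  if (spec$blur_fwhm_mm < 0 || spec$noise_sd < 0)
    stop("blur and noise must be non-negative")
  invisible(spec)
}

#' Ellipsoid semi-axes for a target volume
#'
#' Scales the axis-ratio template `ratios` so the ellipsoid
#' `4/3 * pi * a * b * c` has volume `volume_ml`.
#'
#' @param volume_ml Target volume in ml.
#' @param ratios Relative semi-axis proportions.
#' @return Numeric length-3 semi-axes in mm.
#' @export
radii_for_volume <- function(volume_ml, ratios = c(1, 0.85, 1.15)) {
  s <- (3 * volume_ml * 1000 / (4 * pi * prod(ratios)))^(1 / 3)
  s * ratios
}

## Ellipsoid indicator for a spec, optionally with radii scaled by `scale`.
ellipsoid_mask <- function(spec, scale = 1) {
  d <- spec$grid_shape
  cx <- spec$tumor_center
  sp <- spec$spacing
  r <- spec$tumor_radii_mm * scale
  x <- (((seq_len(d[1]) - cx[1]) * sp[1]) / r[1])^2
  y <- (((seq_len(d[2]) - cx[2]) * sp[2]) / r[2])^2
  z <- (((seq_len(d[3]) - cx[3]) * sp[3]) / r[3])^2
  outer(outer(x, y, "+"), z, "+") <= 1
}

#' Generate a synthetic PET phantom
#'
#' Construction order: ellipsoid indicator scaled to `suv_peak`, multiplied by
#' a normalized textured component `1 + amp * G` (Gaussian random field `G`
#' standardized over tumor voxels, floored at 0.1 and rescaled so its maximum
#' is 1), necrotic-core carving (uptake pulled toward background inside
#' `necrotic_fraction` of the radii), background plateau, Gaussian blur,
#' additive noise, and clamping at zero. Deterministic given `spec$seed`.
#'
#' @param spec A [phantom_spec()].
#' @return A [pet_volume()]; the pre-blur tumor indicator is attached as
#'   attribute `"true_mask"` and the true volume in ml as `"true_volume_ml"`.
#' @export
generate_phantom <- function(spec) {
  validate_phantom_spec(spec)
  d <- spec$grid_shape
  tumor <- ellipsoid_mask(spec)
  ## tumor must sit fully inside the grid
  ext_lo <- spec$tumor_center - spec$tumor_radii_mm / spec$spacing
  ext_hi <- spec$tumor_center + spec$tumor_radii_mm / spec$spacing
  if (any(ext_lo < 1) || any(ext_hi > d))
    stop("tumor not fully inside grid")
  if (!any(tumor)) stop("tumor support is empty at this grid resolution")

  vol <- with_seed(spec$seed, {
    h <- array(1, d)
    if (spec$heterogeneity_amp > 0) {
      g <- gaussian_smooth(array(rnorm(prod(d)), d),
                           spec$texture_corr_len_mm, spec$spacing)
      gt <- g[tumor]
      if (sd(gt) > 0) g <- (g - mean(gt)) / sd(gt)
      h <- 1 + spec$heterogeneity_amp * g
      h[h < 0.1] <- 0.1
      h <- h / max(h[tumor])
    }
    uptake <- spec$suv_peak * h
    v <- array(spec$background_suv, d)
    v[tumor] <- pmax(uptake[tumor], spec$background_suv)
    if (spec$necrotic_fraction > 0) {
      core <- ellipsoid_mask(spec, scale = spec$necrotic_fraction)
      v[core] <- spec$background_suv + 0.15 * (v[core] - spec$background_suv)
    }
    if (spec$blur_fwhm_mm > 0) {
      v <- gaussian_smooth(v, fwhm_to_sigma(spec$blur_fwhm_mm), spec$spacing)
      ## suv_peak targets the measured (post-smoothing) peak, as a clinical
      ## SBR is read off the reconstructed image: restore the blurred peak.
      mx <- max(v)
      if (mx > spec$background_suv)
        v <- spec$background_suv + (v - spec$background_suv) *
          (spec$suv_peak - spec$background_suv) / (mx - spec$background_suv)
    }
    if (spec$noise_sd > 0)
      v <- v + array(rnorm(prod(d), sd = spec$noise_sd), d)
    pmax(v, 0)
  })
  out <- pet_volume(vol, spacing = spec$spacing)
  attr(out, "true_mask") <- tumor
  attr(out, "true_volume_ml") <- sum(tumor) * prod(spec$spacing) / 1000
  out
}

#' Generate a phantom cohort
#'
#' Tumor volumes are drawn log-uniformly over `size_range_ml`; with
#' probability `small_fraction` a tumor is instead drawn below the 64-voxel
#' analyzability floor (so the cohort reproduces the exclusion pattern of a
#' clinical series containing small lesions). Per-patient signal-to-background
#' ratios are drawn from a truncated normal emulating a real series
#' (mean 23.5, SD 7.4, floor 5); larger tumors may receive a necrotic core.
#' All per-patient seeds derive from `seed`.
#'
#' @param n_patients Number of phantoms.
#' @param base_spec Template [phantom_spec()] (grid, spacing, blur, noise,
#'   texture parameters).
#' @param size_range_ml Range (ml) for the log-uniform tumor volume draw.
#' @param small_fraction Proportion of tumors drawn below the 64-voxel floor.
#' @param seed Cohort RNG seed.
#' @param sbr_mean,sbr_sd,sbr_min Parameters of the truncated-normal draw of
#'   per-patient target SBR.
#' @param necrosis_prob Probability that a tumor of at least 8 ml receives a
#'   necrotic core (fraction 0.4 of the radii).
#' @return List with one entry per patient: `patient`, `volume`
#'   ([pet_volume()]), `true_mask` ([voi_mask()], method `"TRUTH"`),
#'   `seed_point` (nominal click, voxel coords), `true_volume_ml`, `spec`.
#' @export
generate_cohort <- function(n_patients = 43, base_spec = phantom_spec(),
                            size_range_ml = c(1, 60), small_fraction = 0.3,
                            seed = 1L, sbr_mean = 23.5, sbr_sd = 7.4,
                            sbr_min = 5, necrosis_prob = 0.3) {
  stopifnot(n_patients >= 1, small_fraction >= 0, small_fraction < 1)
  floor_ml <- 64 * prod(base_spec$spacing) / 1000
  if (size_range_ml[1] <= 0 || size_range_ml[2] <= size_range_ml[1])
    stop("invalid size range")
  if (size_range_ml[2] <= floor_ml && small_fraction < 1)
    stop("size range incompatible with the 64-voxel floor")
  draws <- with_seed(seed, {
    lapply(seq_len(n_patients), function(i) {
      small <- runif(1) < small_fraction
      lo <- log(size_range_ml[1]); hi <- log(size_range_ml[2])
      vol_ml <- if (small) {
        exp(runif(1, lo, log(max(floor_ml, size_range_ml[1] * 1.01))))
      } else {
        exp(runif(1, log(max(floor_ml, size_range_ml[1])), hi))
      }
      sbr <- rnorm(1, sbr_mean, sbr_sd)
      while (sbr < sbr_min) sbr <- rnorm(1, sbr_mean, sbr_sd)
      ratios <- c(1, 0.85, 1.15) * exp(runif(3, -0.1, 0.1))
      necro <- if (vol_ml >= 8 && runif(1) < necrosis_prob) 0.4 else 0
      list(vol_ml = vol_ml, sbr = sbr, ratios = ratios, necro = necro,
           seed = sample.int(.Machine$integer.max - 1L, 1))
    })
  })
  lapply(seq_len(n_patients), function(i) {
    dr <- draws[[i]]
    spec <- base_spec
    spec$tumor_radii_mm <- radii_for_volume(dr$vol_ml, dr$ratios)
    spec$target_sbr <- dr$sbr
    spec$suv_peak <- dr$sbr * spec$background_suv
    spec$necrotic_fraction <- dr$necro
    spec$seed <- dr$seed
    validate_phantom_spec(spec)
    vol <- generate_phantom(spec)
    tm <- voi_mask(attr(vol, "true_mask"), vol, method = "TRUTH",
                   observer = "truth")
    list(patient = sprintf("P%02d", i), volume = vol, true_mask = tm,
         seed_point = round(spec$tumor_center),
         true_volume_ml = attr(vol, "true_volume_ml"), spec = spec)
  })
}

#' Simulate an observer's seed click
#'
#' Displaces the nominal seed point by a random vector of magnitude at most
#' `jitter_mm` (uniform in the ball), constrained to stay inside the tumor
#' support; emulates two readers who initiate segmentation at slightly
#' different positions.
#'
#' @param nominal_seed_point Voxel coordinates of the nominal click.
#' @param jitter_mm Maximum displacement magnitude in mm (>= 0).
#' @param observer_seed RNG seed for this observer's draw.
#' @param support Logical 3D array of allowed seed positions (the true tumor
#'   support).
#' @param spacing Voxel spacing in mm.
#' @param observer Observer identifier.
#' @param max_retries Attempts before giving up.
#' @return Object of class `observer_action`: `observer`, `seed_point`,
#'   `jitter_mm`.
#' @export
simulate_observer <- function(nominal_seed_point, jitter_mm, observer_seed,
                              support, spacing = c(4.07, 4.07, 2),
                              observer = "obs", max_retries = 50L) {
  stopifnot(jitter_mm >= 0)
  nominal_seed_point <- round(nominal_seed_point)
  if (!support[matrix(nominal_seed_point, 1)])
    stop("nominal seed point lies outside the tumor support")
  pt <- nominal_seed_point
  if (jitter_mm > 0) {
    pt <- with_seed(observer_seed, {
      found <- NULL
      for (k in seq_len(max_retries)) {
        u <- rnorm(3)
        u <- u / sqrt(sum(u^2))
        r <- jitter_mm * runif(1)^(1 / 3)
        cand <- round(nominal_seed_point + r * u / spacing)
        inside <- all(cand >= 1) && all(cand <= dim(support)) &&
          support[matrix(cand, 1)]
        if (inside) { found <- cand; break }
      }
      if (is.null(found))
        stop("could not place a jittered seed inside the tumor support")
      found
    })
  }
  structure(list(observer = as.character(observer), seed_point = pt,
                 jitter_mm = jitter_mm),
            class = "observer_action")
}

#' Write a cohort to disk
#'
#' Emits one NIfTI volume and one NIfTI ground-truth mask per phantom plus a
#' CSV manifest (patient id, seed, true volume in ml, nominal seed point).
#'
#' @param cohort Output of [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @return Path of the manifest CSV, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(cohort, function(p) {
    save_volume(p$volume, file.path(dir, paste0(p$patient, "_pet.nii.gz")))
    save_mask(p$true_mask, file.path(dir, paste0(p$patient, "_truth.nii.gz")))
    data.frame(patient = p$patient, seed = p$spec$seed,
               true_volume_ml = p$true_volume_ml,
               seed_x = p$seed_point[1], seed_y = p$seed_point[2],
               seed_z = p$seed_point[3])
  })
  manifest <- do.call(rbind, rows)
  path <- file.path(dir, "manifest.csv")
  write.csv(manifest, path, row.names = FALSE)
  invisible(path)
}
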