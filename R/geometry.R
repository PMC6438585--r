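## Internal geometry utilities shared by the generator, the segmentation
## methods and the texture builders. All work on plain 3D arrays; physical
## coordinates are voxel index (1-based) scaled by spacing in mm.

fwhm_to_sigma <- function(fwhm) fwhm / (2 * sqrt(2 * log(2)))

## Shift a 3D array by k cells along one axis, replicating the edge plane.
shift_axis <- function(a, k, axis) {
  n <- dim(a)[axis]
  idx <- pmin(pmax(seq_len(n) + k, 1L), n)
  switch(axis,
    a[idx, , , drop = FALSE],
    a[, idx, , drop = FALSE],
    a[, , idx, drop = FALSE])
}

## Shift by k cells along an axis, filling with `fill` instead of replicating.
shift_axis_fill <- function(a, k, axis, fill = 0) {
  n <- dim(a)[axis]
  out <- array(fill, dim(a))
  if (abs(k) >= n) return(out)
  src <- if (k >= 0) seq_len(n - k) else seq.int(1 - k, n)
  dst <- if (k >= 0) seq.int(1 + k, n) else seq_len(n + k)
  switch(axis,
    out[dst, , ] <- a[src, , , drop = FALSE],
    out[, dst, ] <- a[, src, , drop = FALSE],
    out[, , dst] <- a[, , src, drop = FALSE])
  out
}

## Shift a 3D array by an integer offset (dx, dy, dz), zero filled.
shift3 <- function(a, d, fill = 0) {
  out <- a
  for (ax in 1:3) if (d[ax] != 0L) out <- shift_axis_fill(out, d[ax], ax, fill)
  out
}

## Separable Gaussian smoothing with per-axis sigma in mm. Edge handling is
## kernel renormalization via replicate padding, adequate for plateaued
## backgrounds.
gaussian_smooth <- function(a, sigma_mm, spacing) {
  sigma_mm <- rep(sigma_mm, length.out = 3)
  for (ax in 1:3) {
    s_vox <- sigma_mm[ax] / spacing[ax]
    if (s_vox <= 1e-8) next
    r <- max(1L, ceiling(3 * s_vox))
    w <- exp(-0.5 * ((-r:r) / s_vox)^2)
    w <- w / sum(w)
    acc <- array(0, dim(a))
    for (k in -r:r) acc <- acc + w[k + r + 1] * shift_axis(a, k, ax)
    a <- acc
  }
  a
}

## Squared physical distance of every voxel from a (possibly fractional)
## voxel-coordinate center.
dist2_from <- function(dims, center_vox, spacing) {
  x2 <- ((seq_len(dims[1]) - center_vox[1]) * spacing[1])^2
  y2 <- ((seq_len(dims[2]) - center_vox[2]) * spacing[2])^2
  z2 <- ((seq_len(dims[3]) - center_vox[3]) * spacing[3])^2
  outer(outer(x2, y2, "+"), z2, "+")
}

## Logical sphere of physical radius around a voxel center.
sphere_region <- function(dims, center_vox, radius_mm, spacing) {
  dist2_from(dims, center_vox, spacing) <= radius_mm^2
}

## Trilinear interpolation at continuous voxel coordinates (1-based),
## clamped to the grid (replicate padding beyond the edge).
trilinear <- function(a, pts) {
  d <- dim(a)
  px <- pmin(pmax(pts[, 1], 1), d[1])
  py <- pmin(pmax(pts[, 2], 1), d[2])
  pz <- pmin(pmax(pts[, 3], 1), d[3])
  x0 <- pmin(floor(px), d[1] - 1L); x1 <- x0 + 1
  y0 <- pmin(floor(py), d[2] - 1L); y1 <- y0 + 1
  z0 <- pmin(floor(pz), d[3] - 1L); z1 <- z0 + 1
  fx <- px - x0; fy <- py - y0; fz <- pz - z0
  at <- function(i, j, k) a[cbind(i, j, k)]
  v000 <- at(x0, y0, z0); v100 <- at(x1, y0, z0)
  v010 <- at(x0, y1, z0); v110 <- at(x1, y1, z0)
  v001 <- at(x0, y0, z1); v101 <- at(x1, y0, z1)
  v011 <- at(x0, y1, z1); v111 <- at(x1, y1, z1)
  v00 <- v000 * (1 - fx) + v100 * fx
  v10 <- v010 * (1 - fx) + v110 * fx
  v01 <- v001 * (1 - fx) + v101 * fx
  v11 <- v011 * (1 - fx) + v111 * fx
  v0 <- v00 * (1 - fy) + v10 * fy
  v1 <- v01 * (1 - fy) + v11 * fy
  v0 * (1 - fz) + v1 * fz
}

## Quasi-uniform unit directions on the sphere (Fibonacci lattice), optionally
## rotated so the lattice pole aligns with `axis`.
fib_sphere_dirs <- function(n, axis = NULL) {
  i <- seq_len(n) - 0.5
  phi <- pi * (1 + sqrt(5)) * i
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  dirs <- cbind(r * cos(phi), r * sin(phi), z)
  if (!is.null(axis)) {
    nrm <- sqrt(sum(axis^2))
    if (nrm > 1e-9) dirs <- dirs %*% t(rotation_from_z(axis / nrm))
  }
  dirs
}

## Rotation matrix mapping the +z unit vector onto unit vector u.
rotation_from_z <- function(u) {
  z <- c(0, 0, 1)
  v <- c(z[2] * u[3] - z[3] * u[2], z[3] * u[1] - z[1] * u[3], z[1] * u[2] - z[2] * u[1])
  c_ <- sum(z * u)
  if (abs(c_ + 1) < 1e-12) return(diag(c(1, -1, -1)))  # antipodal: flip
  vx <- matrix(c(0, v[3], -v[2], -v[3], 0, v[1], v[2], -v[1], 0), 3, 3)
  diag(3) + vx + vx %*% vx / (1 + c_)
}

## One-step 26-neighborhood dilation / erosion of a logical array.
dilate26 <- function(mask) {
  acc <- mask
  for (d in neighbor_offsets_26())
    acc <- acc | shift3(mask, d, fill = FALSE)
  acc
}

erode26 <- function(mask) {
  acc <- mask
  for (d in neighbor_offsets_26())
    acc <- acc & shift3(mask, d, fill = FALSE)
  acc
}

## The 13 unique lattice directions (one per +/- pair) at Chebyshev distance 1.
offsets_13 <- function() {
  list(
    c(1L, 0L, 0L), c(0L, 1L, 0L), c(0L, 0L, 1L),
    c(1L, 1L, 0L), c(1L, -1L, 0L),
    c(1L, 0L, 1L), c(1L, 0L, -1L),
    c(0L, 1L, 1L), c(0L, 1L, -1L),
    c(1L, 1L, 1L), c(1L, 1L, -1L), c(1L, -1L, 1L), c(1L, -1L, -1L))
}

neighbor_offsets_26 <- function() {
  out <- vector("list", 26L)
  i <- 0L
  for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
    if (dx == 0 && dy == 0 && dz == 0) next
    i <- i + 1L
    out[[i]] <- c(dx, dy, dz)
  }
  out
}

## Bounding box of a logical array, padded by `pad` voxels and clipped to the
## grid. Returns a list of index vectors, or NULL for an empty mask.
bbox_of <- function(mask, pad = 0L) {
  w <- which(mask, arr.ind = TRUE)
  if (nrow(w) == 0) return(NULL)
  d <- dim(mask)
  lo <- pmax(apply(w, 2, min) - pad, 1L)
  hi <- pmin(apply(w, 2, max) + pad, d)
  list(x = lo[1]:hi[1], y = lo[2]:hi[2], z = lo[3]:hi[3])
}

## Voxels of the mask with at least one 26-neighbor outside the mask.
mask_boundary <- function(mask) mask & !erode26(mask)

## Logical shell of voxels whose physical distance to the mask lies in
## (guard_mm, guard_mm + thickness_mm]. Distances are measured to the nearest
## mask voxel center, anisotropy respected.
distance_shell <- function(mask, spacing, guard_mm, thickness_mm) {
  d <- dim(mask)
  pad <- ceiling((guard_mm + thickness_mm) / min(spacing)) + 1L
  bb <- bbox_of(mask, pad = pad)
  shell <- array(FALSE, d)
  if (is.null(bb)) return(shell)
  sub <- mask[bb$x, bb$y, bb$z]
  bnd <- which(mask_boundary_or_all(sub), arr.ind = TRUE)
  cand <- which(!sub, arr.ind = TRUE)
  if (nrow(cand) == 0 || nrow(bnd) == 0) return(shell)
  bp <- sweep(bnd, 2, spacing, "*")
  lim_lo2 <- guard_mm^2
  lim_hi2 <- (guard_mm + thickness_mm)^2
  keep <- logical(nrow(cand))
  chunk <- max(1L, floor(4e6 / nrow(bp)))
  for (s in seq(1, nrow(cand), by = chunk)) {
    e <- min(s + chunk - 1L, nrow(cand))
    cp <- sweep(cand[s:e, , drop = FALSE], 2, spacing, "*")
    d2 <- outer(rowSums(cp^2), rowSums(bp^2), "+") - 2 * cp %*% t(bp)
    m2 <- apply(d2, 1, min)
    keep[s:e] <- m2 > lim_lo2 & m2 <= lim_hi2
  }
  kc <- cand[keep, , drop = FALSE]
  if (nrow(kc) > 0) {
    kc[, 1] <- kc[, 1] + bb$x[1] - 1L
    kc[, 2] <- kc[, 2] + bb$y[1] - 1L
    kc[, 3] <- kc[, 3] + bb$z[1] - 1L
    shell[kc] <- TRUE
  }
  shell
}

## Boundary of a cropped mask; falls back to the full mask when erosion
## empties it (very small masks).
mask_boundary_or_all <- function(mask) {
  b <- mask_boundary(mask)
  if (!any(b)) mask else b
}
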