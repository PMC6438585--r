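# Literal brute-force oracles for the four texture matrices, written as
# nested-loop enumerations independent of the package's vectorized builders,
# plus small fixture constructors shared across test files.

# A pet_volume wrapping an arbitrary array (values clipped at 0).
vol_from <- function(arr, spacing = c(1, 1, 1)) {
  pet_volume(array(pmax(arr, 0), dim(arr)), spacing = spacing)
}

# A discretized_voi built directly from an integer level array (0 = outside).
dvoi_from <- function(levels, n_levels = 64L, spacing = c(1, 1, 1)) {
  structure(list(levels = array(as.integer(levels), dim(levels)),
                 n_levels = as.integer(n_levels),
                 n_voxels = sum(levels > 0), spacing = spacing),
            class = "discretized_voi")
}

# Random masked level map on a small grid.
random_dvoi <- function(dims = c(5, 5, 5), n_levels = 4L, p_mask = 0.7) {
  lev <- array(0L, dims)
  m <- array(runif(prod(dims)) < p_mask, dims)
  lev[m] <- sample.int(n_levels, sum(m), replace = TRUE)
  dvoi_from(lev, n_levels = n_levels)
}

all_offsets_26 <- local({
  out <- list()
  for (dz in -1:1) for (dy in -1:1) for (dx in -1:1)
    if (!(dx == 0 && dy == 0 && dz == 0)) out[[length(out) + 1]] <- c(dx, dy, dz)
  out
})

dirs_13 <- all_offsets_26[sapply(all_offsets_26, function(d) {
  d[1] > 0 || (d[1] == 0 && d[2] > 0) || (d[1] == 0 && d[2] == 0 && d[3] > 0)
})]

in_grid <- function(p, d) all(p >= 1) && all(p <= d)

# GLCM oracle: double loop over every voxel and every one of the 26 ordered
# offsets; counts pairs with both endpoints in the mask.
oracle_glcm <- function(dvoi) {
  lev <- dvoi$levels
  d <- dim(lev)
  n <- dvoi$n_levels
  counts <- matrix(0, n, n)
  for (x in 1:d[1]) for (y in 1:d[2]) for (z in 1:d[3]) {
    i <- lev[x, y, z]
    if (i == 0) next
    for (off in all_offsets_26) {
      q <- c(x, y, z) + off
      if (!in_grid(q, d)) next
      j <- lev[q[1], q[2], q[3]]
      if (j == 0) next
      counts[i, j] <- counts[i, j] + 1
    }
  }
  counts
}

# GLRLM oracle: for each of 13 directions, start a run at any voxel without a
# same-level in-mask predecessor along -d, then extend along +d.
oracle_glrlm <- function(dvoi) {
  lev <- dvoi$levels
  d <- dim(lev)
  runs <- list()
  for (dd in dirs_13) {
    for (x in 1:d[1]) for (y in 1:d[2]) for (z in 1:d[3]) {
      i <- lev[x, y, z]
      if (i == 0) next
      prev <- c(x, y, z) - dd
      if (in_grid(prev, d) && lev[prev[1], prev[2], prev[3]] == i) next
      len <- 1
      q <- c(x, y, z) + dd
      while (in_grid(q, d) && lev[q[1], q[2], q[3]] == i) {
        len <- len + 1
        q <- q + dd
      }
      runs[[length(runs) + 1]] <- c(i, len)
    }
  }
  rr <- do.call(rbind, runs)
  mat <- matrix(0, dvoi$n_levels, max(rr[, 2]))
  for (k in seq_len(nrow(rr))) mat[rr[k, 1], rr[k, 2]] <- mat[rr[k, 1], rr[k, 2]] + 1
  mat
}

# NGLDM oracle: per-voxel neighbor enumeration.
oracle_ngldm_Q <- function(dvoi) {
  lev <- dvoi$levels
  d <- dim(lev)
  n <- dvoi$n_levels
  Q <- matrix(0, n, 27)
  for (x in 1:d[1]) for (y in 1:d[2]) for (z in 1:d[3]) {
    i <- lev[x, y, z]
    if (i == 0) next
    dep <- 0
    for (off in all_offsets_26) {
      q <- c(x, y, z) + off
      if (in_grid(q, d) && lev[q[1], q[2], q[3]] == i) dep <- dep + 1
    }
    Q[i, dep + 1] <- Q[i, dep + 1] + 1
  }
  Q
}

# GLZLM oracle: flood fill over equal-level 26-neighbors.
oracle_glzlm <- function(dvoi) {
  lev <- dvoi$levels
  d <- dim(lev)
  seen <- array(FALSE, d)
  zones <- list()
  for (x in 1:d[1]) for (y in 1:d[2]) for (z in 1:d[3]) {
    i <- lev[x, y, z]
    if (i == 0 || seen[x, y, z]) next
    stack <- list(c(x, y, z))
    seen[x, y, z] <- TRUE
    size <- 0
    while (length(stack) > 0) {
      p <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      size <- size + 1
      for (off in all_offsets_26) {
        q <- p + off
        if (in_grid(q, d) && !seen[q[1], q[2], q[3]] &&
            lev[q[1], q[2], q[3]] == i) {
          seen[q[1], q[2], q[3]] <- TRUE
          stack[[length(stack) + 1]] <- q
        }
      }
    }
    zones[[length(zones) + 1]] <- c(i, size)
  }
  zz <- do.call(rbind, zones)
  mat <- matrix(0, dvoi$n_levels, max(zz[, 2]))
  for (k in seq_len(nrow(zz))) mat[zz[k, 1], zz[k, 2]] <- mat[zz[k, 1], zz[k, 2]] + 1
  mat
}

# Pad a matrix with zero columns so dimensions agree before comparison.
pad_cols <- function(m, ncols) {
  if (ncol(m) < ncols) m <- cbind(m, matrix(0, nrow(m), ncols - ncol(m)))
  m
}

expect_matrix_equal <- function(a, b) {
  nc <- max(ncol(a), ncol(b))
  expect_equal(unname(pad_cols(a, nc)), unname(pad_cols(b, nc)),
               ignore_attr = TRUE)
}

# Dilate a logical mask by `steps` 26-neighborhood shells (test-local
# implementation used to carve out the blur tail around the true tumor).
dilate_truth <- function(mask, steps = 3) {
  d <- dim(mask)
  for (s in seq_len(steps)) {
    acc <- mask
    for (off in all_offsets_26) {
      shifted <- array(FALSE, d)
      xs <- pmax(1, 1 - off[1]):pmin(d[1], d[1] - off[1])
      ys <- pmax(1, 1 - off[2]):pmin(d[2], d[2] - off[2])
      zs <- pmax(1, 1 - off[3]):pmin(d[3], d[3] - off[3])
      shifted[xs + off[1], ys + off[2], zs + off[3]] <- mask[xs, ys, zs]
      acc <- acc | shifted
    }
    mask <- acc
  }
  mask
}
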