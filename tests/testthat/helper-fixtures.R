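# Fixtures are built in code; nothing is stored on disk.

# random porous mask: smoothed white noise thresholded at a quantile
rand_smooth_mask <- function(dims, seed, frac = 0.3, sigma = 1.5, voxel_mm = 1) {
  set.seed(seed)
  r <- array(rnorm(prod(dims)), dims)
  r <- trabmorph:::cpp_gauss_blur(r, as.integer(dims), rep(sigma, 3))
  binary_volume(r > quantile(r, 1 - frac), voxel_mm)
}

rand_slice8 <- function(ny, nx, seed) {
  set.seed(seed)
  matrix(sample(0:255, ny * nx, replace = TRUE), ny, nx)
}

# O(n^2) squared-EDT oracle: min squared distance from each in-phase voxel to
# any off-phase voxel centre, with a one-voxel off-phase border around the
# volume (independent of the package's scan-based transform)
edt2_brute_r <- function(mask) {
  d <- dim(mask)
  idx <- which(mask, arr.ind = TRUE)
  off <- which(!mask, arr.ind = TRUE)
  # off-phase border voxels: faces just outside the volume
  border <- rbind(
    cbind(0, rep(seq_len(d[2]), each = d[3]), rep(seq_len(d[3]), d[2])),
    cbind(d[1] + 1, rep(seq_len(d[2]), each = d[3]), rep(seq_len(d[3]), d[2])),
    cbind(rep(seq_len(d[1]), each = d[3]), 0, rep(seq_len(d[3]), d[1])),
    cbind(rep(seq_len(d[1]), each = d[3]), d[2] + 1, rep(seq_len(d[3]), d[1])),
    cbind(rep(seq_len(d[1]), each = d[2]), rep(seq_len(d[2]), d[1]), 0),
    cbind(rep(seq_len(d[1]), each = d[2]), rep(seq_len(d[2]), d[1]), d[3] + 1))
  tgt <- rbind(off, border)
  out <- array(0, d)
  for (k in seq_len(nrow(idx))) {
    p <- idx[k, ]
    out[p[1], p[2], p[3]] <-
      min((tgt[, 1] - p[1])^2 + (tgt[, 2] - p[2])^2 + (tgt[, 3] - p[3])^2)
  }
  out
}

# direct 2D 3x3 convolution with replicate edges (oracle for the sharpen kernel)
conv3x3_r <- function(slice, kernel) {
  ny <- nrow(slice); nx <- ncol(slice)
  out <- matrix(0, ny, nx)
  cl <- function(v, n) pmin(pmax(v, 1), n)
  for (y in seq_len(ny)) for (x in seq_len(nx)) {
    acc <- 0
    for (dy in -1:1) for (dx in -1:1)
      acc <- acc + kernel[dy + 2, dx + 2] * slice[cl(y + dy, ny), cl(x + dx, nx)]
    out[y, x] <- acc
  }
  out
}

med3x3_r <- function(slice) {
  ny <- nrow(slice); nx <- ncol(slice)
  out <- matrix(0, ny, nx)
  cl <- function(v, n) pmin(pmax(v, 1), n)
  for (y in seq_len(ny)) for (x in seq_len(nx)) {
    v <- numeric(9); k <- 0
    for (dy in -1:1) for (dx in -1:1) {
      k <- k + 1
      v[k] <- slice[cl(y + dy, ny), cl(x + dx, nx)]
    }
    out[y, x] <- median(v)
  }
  out
}

# Exhaustive mid-bin isodata oracle for small integer-valued samples: iterate
# the partition map (threshold between consecutive distinct values) from the
# mean until it is a fixed point; returns the class boundary (largest value of
# the lower class). Implemented on partitions, not on the tolerance loop the
# package uses.
iso_partition_oracle <- function(v) {
  u <- sort(unique(v))
  stopifnot(length(u) >= 2)
  boundary_from_t <- function(t) max(which(u <= t)) # index into u, lower class
  b <- boundary_from_t(mean(v))
  b <- min(max(b, 1L), length(u) - 1L)
  for (iter in 1:1000) {
    lower <- v[v <= u[b]]
    upper <- v[v > u[b]]
    g <- (mean(lower) + mean(upper)) / 2
    b2 <- boundary_from_t(g)
    b2 <- min(max(b2, 1L), length(u) - 1L)
    if (b2 == b) return(list(boundary_value = u[b], midpoint = g))
    b <- b2
  }
  stop("partition iteration did not settle")
}

# 6-connected binary dilation (used by the monotonicity properties)
dilate6 <- function(m) {
  d <- dim(m); out <- m
  out[-1, , ] <- out[-1, , ] | m[-d[1], , ]
  out[-d[1], , ] <- out[-d[1], , ] | m[-1, , ]
  out[, -1, ] <- out[, -1, ] | m[, -d[2], ]
  out[, -d[2], ] <- out[, -d[2], ] | m[, -1, ]
  out[, , -1] <- out[, , -1] | m[, , -d[3]]
  out[, , -d[3]] <- out[, , -d[3]] | m[, , -1]
  out
}

# tiny phantom used across tests (kept small so the suite stays fast)
tiny_phantom <- function(seed = 11, target = 0.25, texture = 5, air = 0.2) {
  generate_trabecular_phantom(
    phantom_spec(c(1, 1, 2), 0.02, target, 0.1, seed = seed),
    intensity_model(texture_sigma = texture), air_fraction = air)
}

# smoke-scale experiment config
smoke_config <- function(n = 3, seed = 5, out_dir = NULL,
                         params = c("bv_tv", "tb_th", "tb_n", "tb_sp")) {
  cfg <- default_config(n = n, seed = seed, out_dir = out_dir)
  cfg$phantom$shape_mm <- c(1.6, 1.6, 2.6)
  cfg$roi$extent_mm <- c(1, 1, 2)
  cfg$roi$ball_radius_mm <- 0.4
  cfg$params <- params
  cfg
}
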