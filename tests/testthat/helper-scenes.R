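# Shared fixtures and independent oracles, built in code at test time.

# small contact scene: 4 cilia, clean rasters unless noise requested
small_scene_params <- function(seed = 1L, noise = FALSE, blur = FALSE,
                               n_scatter_nuclei = 1L, boundary_cilium = TRUE, ...) {
  scene_params(n_cilia = 4L, n_scatter_nuclei = n_scatter_nuclei,
               boundary_cilium = boundary_cilium,
               noise = noise, blur = blur, seed = seed, ...)
}

# brute-force Euclidean distance transform: for every voxel, the minimum
# distance to any TRUE voxel of the target (exhaustive all-pairs scan)
brute_force_edt <- function(target, spacing) {
  d <- dim(target)
  idx <- which(target, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(array(Inf, d))
  pts <- sweep(idx, 2L, spacing, "*")
  out <- array(0, d)
  for (z in seq_len(d[1])) for (y in seq_len(d[2])) for (x in seq_len(d[3])) {
    p <- c(z, y, x) * spacing
    out[z, y, x] <- sqrt(min(colSums((t(pts) - p)^2)))
  }
  out
}

# match each skeleton instance to the nearest generator truth path
match_to_paths <- function(skels, paths) {
  vapply(skels$coords, function(co) {
    which.min(vapply(paths, function(pp) {
      dd <- outer(rowSums(co^2), rowSums(pp^2), "+") - 2 * co %*% t(pp)
      sqrt(max(min(dd), 0))
    }, numeric(1)))
  }, integer(1))
}

# brute-force Otsu: exhaustive search of the between-class variance
# maximizer over all candidate bin edges
brute_force_otsu <- function(v, n_bins = 256L) {
  rng <- range(v)
  brk <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  best <- -Inf; best_t <- NA_real_
  for (k in seq_len(n_bins - 1L)) {
    thr <- brk[k + 1L]
    lo <- v[v < thr]; hi <- v[v >= thr]
    if (length(lo) == 0L || length(hi) == 0L) next
    bcv <- length(lo) * length(hi) * (mean(hi) - mean(lo))^2
    if (bcv > best) { best <- bcv; best_t <- thr }
  }
  best_t
}

# rasterized image of parallel stripes running along `theta_deg`
stripe_image <- function(theta_deg, n = 200L, lambda = 12) {
  th <- theta_deg * pi / 180
  y <- matrix(seq_len(n), n, n)
  x <- t(y)
  sin(2 * pi * (-sin(th) * x + cos(th) * y) / lambda)
}

# plant isotropic 3D Gaussian spots of sigma (voxels) at integer positions
plant_spots <- function(dim_zyx, positions, sigma_vox = 2, amplitude = 1) {
  arr <- array(0, dim_zyx)
  r <- ceiling(3 * sigma_vox)
  g <- expand.grid(z = -r:r, y = -r:r, x = -r:r)
  w <- amplitude * exp(-(g$z^2 + g$y^2 + g$x^2) / (2 * sigma_vox^2))
  for (i in seq_len(nrow(positions))) {
    v <- positions[i, ]
    idx <- cbind(v[1] + g$z, v[2] + g$y, v[3] + g$x)
    ok <- idx[, 1] >= 1 & idx[, 1] <= dim_zyx[1] &
      idx[, 2] >= 1 & idx[, 2] <= dim_zyx[2] &
      idx[, 3] >= 1 & idx[, 3] <= dim_zyx[3]
    arr[idx[ok, , drop = FALSE]] <- arr[idx[ok, , drop = FALSE]] + w[ok]
  }
  arr
}
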