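#' z-plane flat-field correction vector
#'
#' Estimates depth-dependent intensity attenuation (antibody penetration)
#' from one or more stained channels: each volume is mean-projected
#' through y to an x-z plane, normalized to its maximum, the planes are
#' averaged across channels, smoothed with a 2D Gaussian (default
#' sigma = 2 px) to prevent sudden intensity variations, averaged through
#' x, and finally normalized by the maximum. The result is a per-z-plane
#' correction vector with values in (0, 1] and max 1.
#'
#' @param vols a [voxel_volume()] or list of them on one grid (>= 3 z
#'   planes).
#' @param gaussian_sigma smoothing sigma in px (> 0).
#' @return numeric vector of length `nz`.
#' @export
flatfield_z <- function(vols, gaussian_sigma = 2) {
  if (inherits(vols, "voxel_volume")) vols <- list(vols)
  stopifnot(length(vols) >= 1L, gaussian_sigma > 0)
  d <- dim(vols[[1L]]$values)
  if (d[1] < 3L) stop("need >= 3 z planes")
  planes <- lapply(vols, function(v) {
    xz <- apply(v$values, c(1, 3), mean)       # mean through y -> (z, x)
    mx <- max(xz)
    if (mx <= 0) stop("channel is entirely zero")
    xz / mx
  })
  avg <- Reduce(`+`, planes) / length(planes)
  sm <- gauss2(avg, gaussian_sigma)
  vec <- rowMeans(sm)
  if (any(vec <= 0)) stop("flat-field vector undefined: a z plane is entirely zero")
  vec / max(vec)
}

#' Apply a z flat-field correction vector
#'
#' Divides each z plane of the volume by its correction-vector entry.
#'
#' @param vol a [voxel_volume()].
#' @param vector correction vector of length `nz`, all entries > 0.
#' @return The corrected `voxel_volume`.
#' @export
apply_flatfield <- function(vol, vector) {
  stopifnot(inherits(vol, "voxel_volume"))
  d <- dim(vol$values)
  if (length(vector) != d[1]) stop("vector length must equal the number of z planes")
  if (any(vector <= 0)) stop("correction vector entries must be > 0")
  out <- vol$values / array(vector, d)   # recycles along z (first dim)
  voxel_volume(out, vol$spacing, channel = vol$channel)
}

#' Voxel-wise marker-to-DNA ratio map
#'
#' Divides the marker channel by the DNA (Hoechst) channel voxel by voxel,
#' restricted to voxels where the DNA signal reaches the restricted-Otsu
#' threshold (Otsu computed on values capped at `cap_percentile`, default
#' the 90th percentile, then applied to all voxels). Other voxels are
#' invalid and excluded from summaries.
#'
#' @param marker,dna [voxel_volume()]s on one (isotropic) grid.
#' @param cap_percentile percentile cap for the denominator threshold.
#' @return list of class `ratio_field`: `ratio` (3D array, NA where
#'   invalid), `valid` (logical array), `den_threshold`, `cap_percentile`,
#'   `spacing`.
#' @export
ratio_map <- function(marker, dna, cap_percentile = 90) {
  stopifnot(inherits(marker, "voxel_volume"), inherits(dna, "voxel_volume"))
  if (!identical(dim(marker$values), dim(dna$values)))
    stop("marker and dna must share a grid")
  thr <- otsu_threshold(dna$values, cap_percentile = cap_percentile)
  valid <- dna$values >= thr
  ratio <- array(NA_real_, dim(marker$values))
  ratio[valid] <- marker$values[valid] / dna$values[valid]
  structure(list(ratio = ratio, valid = valid, den_threshold = thr,
                 cap_percentile = cap_percentile, spacing = marker$spacing),
            class = "ratio_field")
}

#' @export
print.ratio_field <- function(x, ...) {
  cat(sprintf("ratio_field: %d valid voxel(s) (threshold %.4g, cap %gth pct)\n",
              sum(x$valid), x$den_threshold, x$cap_percentile))
  invisible(x)
}

#' Mode of a ratio sample by kernel density estimation
#'
#' Gaussian-kernel density estimate with Scott's-rule bandwidth
#' ([stats::bw.nrd]); the mode is the argmax of the density evaluated on a
#' 2048-point grid spanning the data range. A zero-variance sample returns
#' the common value directly.
#'
#' @param values numeric sample (>= 100 values), e.g. `ratio_field$ratio`
#'   over valid voxels.
#' @param bandwidth optional override of the bandwidth.
#' @return list of class `ratio_summary`: `mode`, `kde_bandwidth`,
#'   `n_values`.
#' @export
kde_mode <- function(values, bandwidth = NULL) {
  values <- values[is.finite(values)]
  if (length(values) < 100L) stop("need >= 100 values for a stable KDE mode")
  if (stats::sd(values) == 0) {
    return(structure(list(mode = values[1], kde_bandwidth = 0,
                          n_values = length(values)), class = "ratio_summary"))
  }
  bw <- if (is.null(bandwidth)) stats::bw.nrd(values) else bandwidth
  den <- stats::density(values, bw = bw, n = 2048,
                        from = min(values), to = max(values))
  structure(list(mode = den$x[which.max(den$y)], kde_bandwidth = bw,
                 n_values = length(values)), class = "ratio_summary")
}

#' @export
print.ratio_summary <- function(x, ...) {
  cat(sprintf("ratio_summary: mode %.4g (bw %.4g, n = %d)\n",
              x$mode, x$kde_bandwidth, x$n_values))
  invisible(x)
}

#' Signed percent change of a mode relative to a reference
#'
#' `round(100 * (new - reference) / reference)` to the nearest integer
#' (half away from zero). The denominator is always the reference
#' (control / baseline) mode; the sign conveys increase vs decrease.
#'
#' @param reference_mode reference (control) mode, > 0.
#' @param new_mode treated-condition mode.
#' @return signed integer percent.
#' @export
percent_change <- function(reference_mode, new_mode) {
  if (reference_mode <= 0) stop("reference mode must be > 0")
  p <- 100 * (new_mode - reference_mode) / reference_mode
  as.integer(sign(p) * floor(abs(p) + 0.5))
}
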