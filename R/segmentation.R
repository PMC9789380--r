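#' Otsu threshold of a volume
#'
#' Classical between-class-variance-maximizing threshold over a 256-bin
#' histogram of the observed intensity range. With `cap_percentile` the
#' histogram (and candidate thresholds) are restricted to values at or below
#' that percentile — the "restricted" variant used to gate dim, skewed DNA
#' stains — but the resulting threshold is applied to all voxels.
#'
#' @param x numeric vector or array of intensities (non-constant).
#' @param cap_percentile optional percentile in (0, 100] restricting the
#'   values used to compute the threshold.
#' @param n_bins histogram bins (default 256).
#' @return the threshold (numeric scalar): foreground is `values >= threshold`.
#' @export
otsu_threshold <- function(x, cap_percentile = NULL, n_bins = 256L) {
  v <- as.numeric(x)
  if (!is.null(cap_percentile)) {
    if (cap_percentile <= 0 || cap_percentile > 100)
      stop("cap_percentile must be in (0, 100]")
    cap <- stats::quantile(v, cap_percentile / 100, names = FALSE, type = 7)
    v <- v[v <= cap]
  }
  rng <- range(v)
  if (rng[1] == rng[2]) stop("constant volume: no Otsu threshold exists")
  # bin values; candidate thresholds are the bin edges
  brk <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  bin <- pmin(pmax(findInterval(v, brk, rightmost.closed = TRUE), 1L), n_bins)
  h <- as.numeric(tabulate(bin, nbins = n_bins))
  vs <- numeric(n_bins)                       # exact per-bin value sums
  agg <- tapply(v, bin, sum)
  vs[as.integer(names(agg))] <- agg
  w <- cumsum(h)
  mu <- cumsum(vs)
  n <- w[n_bins]; mtot <- mu[n_bins]
  w0 <- w[-n_bins]; w1 <- n - w0
  valid <- w0 > 0 & w1 > 0
  num <- (mtot * w0 - mu[-n_bins] * n)^2
  bcv <- ifelse(valid, num / (w0 * w1), -Inf)
  k <- which.max(bcv)          # first maximizer: deterministic tie-break
  brk[k + 1L]                  # threshold at upper edge of bin k
}

#' Otsu foreground mask
#'
#' @param vol a [voxel_volume()] (non-constant).
#' @inheritParams otsu_threshold
#' @return A [binary_mask()] of `values >= threshold`.
#' @export
otsu_mask <- function(vol, cap_percentile = NULL, n_bins = 256L) {
  stopifnot(inherits(vol, "voxel_volume"))
  thr <- otsu_threshold(vol$values, cap_percentile, n_bins)
  binary_mask(vol$values >= thr, vol$spacing)
}

#' Yen's threshold (maximum correlation criterion)
#'
#' Alternative automatic threshold used for dim neuronal FLIM stacks where
#' Otsu over-segments; maximizes Yen's criterion over a 256-bin histogram.
#'
#' @inheritParams otsu_threshold
#' @return the threshold; foreground is `values >= threshold`.
#' @export
yen_threshold <- function(x, n_bins = 256L) {
  v <- as.numeric(x)
  rng <- range(v)
  if (rng[1] == rng[2]) stop("constant volume: no threshold exists")
  brk <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  h <- tabulate(pmin(pmax(findInterval(v, brk, rightmost.closed = TRUE), 1L), n_bins),
                nbins = n_bins)
  p <- h / sum(h)
  P1 <- cumsum(p); P2 <- cumsum(p^2)
  P2r <- sum(p^2) - P2
  P1r <- 1 - P1
  crit <- -log(pmax(P2 * P2r, 1e-300)) + 2 * log(pmax(P1 * P1r, 1e-300))
  crit[P1 <= 0 | P1r <= 0] <- -Inf
  k <- which.max(crit[-n_bins])
  brk[k + 1L]
}

#' Morphological closing and small-object removal
#'
#' Joins fragmented stained structures by closing with a Euclidean ball of
#' `close_radius` um, then removes connected components whose physical
#' volume is below `min_size` um^3 ("no biological relevance" filter).
#'
#' @param mask a [binary_mask()].
#' @param close_radius closing ball radius in um (>= 0).
#' @param min_size minimum component volume in um^3 (>= 0).
#' @param connectivity component connectivity (default 26).
#' @return A cleaned [binary_mask()].
#' @export
close_and_filter <- function(mask, close_radius = 0.4, min_size = 0.05,
                             connectivity = 26L) {
  stopifnot(inherits(mask, "binary_mask"), close_radius >= 0, min_size >= 0)
  out <- if (close_radius > 0) erode_ball(dilate_ball(mask, close_radius), close_radius) else mask
  if (min_size > 0 && any(out$values)) {
    lab <- label_components(out, connectivity)
    sizes <- tabulate(lab[lab > 0L])
    vox_vol <- prod(out$spacing)
    keep <- which(sizes * vox_vol >= min_size)
    out <- binary_mask(array(lab %in% keep, dim(lab)), out$spacing)
  }
  out
}

#' Select the dense cell layer from a nuclei mask
#'
#' Dilates the nuclei mask so that densely packed nuclei (the pyramidal
#' layer) merge, and keeps the largest connected component. Equal-size ties
#' are broken deterministically toward the lowest label and reported.
#'
#' @param nuclei a non-empty [binary_mask()] of nuclei.
#' @param dilate_radius dilation radius in um.
#' @return A [binary_mask()] of the (dilated) layer, always one component.
#' @export
select_layer <- function(nuclei, dilate_radius = 2.0) {
  stopifnot(inherits(nuclei, "binary_mask"))
  if (!any(nuclei$values)) stop("empty nuclei mask")
  dil <- dilate_ball(nuclei, dilate_radius)
  lab <- label_components(dil)
  sizes <- tabulate(lab[lab > 0L])
  big <- which(sizes == max(sizes))
  if (length(big) > 1L)
    message(sprintf("select_layer: %d equal-size components; keeping label %d", length(big), big[1L]))
  binary_mask(lab == big[1L], nuclei$spacing)
}

#' Nucleus centres by erosion and distance-transform splitting
#'
#' Erodes the nuclei mask, computes the Euclidean distance transform inside
#' what remains, thresholds it per component at `split_fraction` of the
#' component's maximum distance to separate touching nuclei, and returns the
#' centroids of the resulting discrete bodies in physical coordinates.
#'
#' @param nuclei a [binary_mask()].
#' @param erode_radius erosion radius in um (>= 0).
#' @param split_fraction fraction in (0, 1) of the per-component maximum
#'   interior distance used as the separating threshold.
#' @return matrix of centroids (rows; columns z, y, x in um); zero rows when
#'   nothing survives erosion (with a warning).
#' @export
nucleus_centers <- function(nuclei, erode_radius = 0.5, split_fraction = 0.5) {
  stopifnot(inherits(nuclei, "binary_mask"),
            erode_radius >= 0, split_fraction > 0, split_fraction < 1)
  er <- erode_ball(nuclei, erode_radius)
  if (!any(er$values)) {
    warning("nucleus_centers: empty mask after erosion")
    return(matrix(numeric(0), 0, 3, dimnames = list(NULL, c("z", "y", "x"))))
  }
  inv <- binary_mask(!er$values, er$spacing)
  dist_in <- distance_to(inv)             # interior depth
  lab <- label_components(er)
  fg <- which(lab > 0L)
  lv <- lab[fg]
  dmax <- tapply(dist_in[fg], lv, max)[lv]  # per-component max, aligned to voxels
  keep <- array(FALSE, dim(lab))
  keep[fg] <- dist_in[fg] >= split_fraction * dmax
  lab2 <- label_components(binary_mask(keep, er$spacing))
  n <- max(lab2)
  idx <- which(lab2 > 0L, arr.ind = TRUE)
  lv2 <- lab2[lab2 > 0L]
  cen <- matrix(0, n, 3, dimnames = list(NULL, c("z", "y", "x")))
  for (a in 1:3)
    cen[, a] <- (tapply((idx[, a] - 0.5) * er$spacing[a], lv2, mean))[as.character(seq_len(n))]
  cen
}
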