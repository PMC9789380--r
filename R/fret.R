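#' FRET ratio time series from a two-channel 4D stack
#'
#' Per frame: (1) maximum-intensity projection along z of donor and
#' sensitized-emission channels; (2) rolling-ball style background
#' flattening of the projected donor (grayscale opening with a disk of
#' `ball_radius` px, subtracted) for mask creation only; (3) Otsu threshold
#' of the flattened donor to segment the cilium; (4) subtraction of the
#' mean intensity of the acellular `bg_region` from both projected
#' channels; (5) FRET ratio = sum(sensitized within mask) /
#' sum(donor within mask). Optional temporal averaging by 2 and a hard
#' low-pass then apply to the ratio trace; `baseline_frames` (e.g. 1:25
#' for direct ligand application, 1:30 for uncaging) yields a dR/R0
#' series.
#'
#' @param donor,sensitized 4D arrays (z, y, x, t) on the same grid.
#' @param bg_region logical (y, x) matrix marking an acellular area.
#' @param ball_radius disk radius in px for background flattening
#'   (default 50).
#' @param temporal_average average frame pairs before filtering.
#' @param lowpass_hz optional low-pass cutoff in Hz (requires `rate_hz`).
#' @param rate_hz acquisition rate in Hz.
#' @param baseline_frames frame indices defining R0 for dR/R0 (optional).
#' @return list of class `fret_series`: `t` (frame index or seconds),
#'   `ratio`, `drr` (when baselined), `flagged` (frames with an empty
#'   mask, ratio NA).
#' @export
fret_ratio_series <- function(donor, sensitized, bg_region,
                              ball_radius = 50, temporal_average = FALSE,
                              lowpass_hz = NULL, rate_hz = NULL,
                              baseline_frames = NULL) {
  dd <- dim(donor)
  if (length(dd) != 4L || !identical(dd, dim(sensitized)))
    stop("donor and sensitized must be 4D (z, y, x, t) arrays on one grid")
  if (!is.matrix(bg_region) || !identical(dim(bg_region), dd[2:3]))
    stop("bg_region must be a logical (y, x) matrix matching the projection")
  nt <- dd[4]
  ratio <- rep(NA_real_, nt)
  flagged <- logical(nt)
  for (k in seq_len(nt)) {
    dproj <- apply(donor[, , , k, drop = FALSE], c(2, 3), max)
    sproj <- apply(sensitized[, , , k, drop = FALSE], c(2, 3), max)
    bgval <- disk_filter2d_cpp(disk_filter2d_cpp(dproj, ball_radius, FALSE),
                               ball_radius, TRUE)     # grayscale opening
    flat <- dproj - bgval
    mask <- tryCatch(flat >= otsu_threshold(flat), error = function(e) NULL)
    if (is.null(mask) || !any(mask)) { flagged[k] <- TRUE; next }
    bsub <- mean(dproj[bg_region]); ssub <- mean(sproj[bg_region])
    dsum <- sum(dproj[mask] - bsub)
    ssum <- sum(sproj[mask] - ssub)
    if (dsum <= 0) { flagged[k] <- TRUE; next }
    ratio[k] <- ssum / dsum
  }
  t <- seq_len(nt)
  if (temporal_average) {
    n <- 2L * (nt %/% 2L)
    i1 <- seq(1L, n, 2L)
    ratio <- (ratio[i1] + ratio[i1 + 1L]) / 2
    t <- (t[i1] + t[i1 + 1L]) / 2
    flagged <- flagged[i1] | flagged[i1 + 1L]
  }
  if (!is.null(lowpass_hz)) {
    if (is.null(rate_hz)) stop("lowpass filtering requires rate_hz")
    if (any(is.na(ratio))) stop("cannot low-pass a ratio trace with flagged frames")
    tr <- lowpass_fourier(sensor_trace(t / rate_hz, ratio), lowpass_hz, rate_hz)
    ratio <- tr$F
    t <- tr$t
  }
  drr <- NULL
  if (!is.null(baseline_frames)) {
    r0 <- mean(ratio[baseline_frames], na.rm = TRUE)
    if (!is.finite(r0) || r0 <= 0) stop("invalid baseline ratio")
    drr <- (ratio - r0) / r0
  }
  structure(list(t = t, ratio = ratio, drr = drr, flagged = flagged),
            class = "fret_series")
}

#' @export
print.fret_series <- function(x, ...) {
  cat(sprintf("fret_series: %d frame(s), %d flagged, ratio range [%.4g, %.4g]\n",
              length(x$t), sum(x$flagged),
              min(x$ratio, na.rm = TRUE), max(x$ratio, na.rm = TRUE)))
  invisible(x)
}
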