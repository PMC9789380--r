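#' Structure-tensor orientation histogram of a 2D image
#'
#' Computes the per-pixel 2D structure tensor from Gaussian-gradient
#' derivatives (scale `grad_sigma`) smoothed with a sliding Gaussian
#' analysis window (`window_sigma`), accumulates an orientation histogram
#' over (-90, 90] degrees weighted by tensor energy (trace) or coherence,
#' and fits a single Gaussian peak to the weighted histogram. Angles are
#' measured from the image x axis toward the y axis; the reported angle is
#' the orientation of elongated structures (perpendicular to the dominant
#' gradient).
#'
#' Fluorescence z stacks are first flattened by maximum-intensity
#' projection; see [max_project()].
#'
#' @param img numeric matrix (rows = y, cols = x), at least 3 x 3,
#'   non-constant.
#' @param grad_sigma Gaussian gradient scale in px (> 0).
#' @param window_sigma analysis-window sigma in px (> 0).
#' @param weighting `"energy"` (tensor trace) or `"coherence"`.
#' @param bin_width histogram bin width in degrees.
#' @return list of class `orientation_result`: `angles` (bin centres, deg),
#'   `weights`, `fit` (center, width, amplitude, offset), and `confident`
#'   (FALSE when the histogram is near flat: amplitude <= offset).
#' @export
orientation_histogram <- function(img, grad_sigma = 2, window_sigma = 20,
                                  weighting = c("energy", "coherence"),
                                  bin_width = 1) {
  weighting <- match.arg(weighting)
  if (!is.matrix(img) || nrow(img) < 3L || ncol(img) < 3L)
    stop("`img` must be a matrix of at least 3 x 3")
  if (grad_sigma <= 0 || window_sigma <= 0) stop("sigmas must be > 0")
  if (max(img) == min(img)) stop("constant image: no orientation signal")
  sm <- gauss2(img, grad_sigma)
  n <- nrow(sm); m <- ncol(sm)
  gy <- (sm[c(2:n, n), ] - sm[c(1, 1:(n - 1)), ]) / 2   # d/dy (rows)
  gx <- (sm[, c(2:m, m)] - sm[, c(1, 1:(m - 1))]) / 2   # d/dx (cols)
  Jxx <- gauss2(gx * gx, window_sigma)
  Jyy <- gauss2(gy * gy, window_sigma)
  Jxy <- gauss2(gx * gy, window_sigma)
  theta <- 0.5 * atan2(2 * Jxy, Jxx - Jyy)              # dominant gradient direction
  struct_deg <- (theta * 180 / pi) + 90                 # structure = gradient + 90 deg
  struct_deg <- ((struct_deg + 90) %% 180) - 90         # wrap to (-90, 90]
  struct_deg[struct_deg <= -90] <- struct_deg[struct_deg <= -90] + 180
  w <- if (weighting == "energy") Jxx + Jyy
       else {
         lam <- sqrt((Jxx - Jyy)^2 + 4 * Jxy^2)
         tr <- Jxx + Jyy
         ifelse(tr > 0, lam / tr, 0)
       }
  edges <- seq(-90, 90, by = bin_width)
  centers <- edges[-1] - bin_width / 2
  bin <- pmin(pmax(findInterval(struct_deg, edges, rightmost.closed = TRUE), 1L),
              length(centers))
  weights <- as.vector(tapply(as.vector(w), factor(bin, levels = seq_along(centers)), sum))
  weights[is.na(weights)] <- 0
  fit <- fit_orientation_gaussian(centers, weights)
  # a meaningful peak must rise above the baseline, be narrower than a
  # quarter period, and carry a substantial share of the histogram mass;
  # isotropic noise fails at least one of these
  peak_mass <- fit["amplitude"] * abs(fit["width"]) * sqrt(2 * pi) /
    max(sum(weights) * bin_width, 1e-300)
  conf <- isTRUE(unname(fit["amplitude"] > fit["offset"] &
                          is.finite(fit["width"]) & fit["width"] < 45 &
                          peak_mass > 0.2))
  structure(list(angles = centers, weights = weights, fit = fit,
                 confident = conf),
            class = "orientation_result")
}

# single-Gaussian fit of a circular (period 180 deg) weighted histogram;
# the histogram is rolled so its argmax sits at the centre before fitting
fit_orientation_gaussian <- function(angles, weights) {
  nb <- length(angles)
  k <- which.max(weights)
  shift <- (nb %/% 2L) - k
  idx <- ((seq_len(nb) - 1L - shift) %% nb) + 1L
  wr <- weights[idx]
  xr <- angles        # rolled histogram now peaks near angles[nb %/% 2]
  off0 <- stats::median(wr)
  amp0 <- max(wr) - off0
  st <- list(center = xr[nb %/% 2L], width = 10, amplitude = max(amp0, 1e-12), offset = off0)
  fit <- tryCatch(
    minpack.lm::nlsLM(wr ~ offset + amplitude * exp(-(xr - center)^2 / (2 * width^2)),
                      start = st,
                      lower = c(center = -90, width = 0.5, amplitude = 0, offset = 0),
                      upper = c(center = 90, width = 180, amplitude = Inf, offset = Inf),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    pars <- c(center = xr[nb %/% 2L], width = NA_real_,
              amplitude = amp0, offset = off0)
  } else {
    pars <- stats::coef(fit)[c("center", "width", "amplitude", "offset")]
  }
  # undo the roll: shifted by `shift` bins of bin_width each
  bw <- if (nb > 1) angles[2] - angles[1] else 1
  cen <- pars[["center"]] - shift * bw
  cen <- ((cen + 90) %% 180) - 90
  if (cen <= -90) cen <- cen + 180
  c(center = cen, width = pars[["width"]],
    amplitude = pars[["amplitude"]], offset = pars[["offset"]])
}

#' @export
print.orientation_result <- function(x, ...) {
  cat(sprintf("orientation_result: fitted center %.1f deg (width %.1f), %s\n",
              x$fit["center"], x$fit["width"],
              if (isTRUE(x$confident)) "confident" else "low confidence (near-flat histogram)"))
  invisible(x)
}

#' Maximum-intensity projection of a volume along z
#'
#' @param vol a [voxel_volume()].
#' @return numeric matrix (y, x).
#' @export
max_project <- function(vol) {
  stopifnot(inherits(vol, "voxel_volume"))
  apply(vol$values, c(2, 3), max)
}
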