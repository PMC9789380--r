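#' Time-stamped fluorescence trace
#'
#' @param t time stamps in seconds, strictly increasing.
#' @param F raw intensity values (same length as `t`).
#' @return An object of class `trace`.
#' @export
sensor_trace <- function(t, F) {
  t <- as.numeric(t); F <- as.numeric(F)
  if (length(t) != length(F)) stop("t and F must have equal length")
  if (any(diff(t) <= 0)) stop("t must be strictly increasing")
  structure(list(t = t, F = F, F0 = NA_real_, dff = NULL,
                 baseline_window = NULL), class = "sensor_trace")
}

#' @export
print.sensor_trace <- function(x, ...) {
  cat(sprintf("trace: %d points over %.3g s%s\n", length(x$t), diff(range(x$t)),
              if (!is.null(x$dff)) sprintf(", F0 = %.4g, dF/F range [%.3g, %.3g]",
                                           x$F0, min(x$dff), max(x$dff)) else ""))
  invisible(x)
}

#' Compute dF/F0 for a trace
#'
#' `F0` is the mean of the background-subtracted intensity over the
#' baseline window (e.g. the 10 frames before photostimulation, or the
#' first 5 frames before ligand application), and
#' `dff = (F - background - F0) / F0`.
#'
#' @param tr a [sensor_trace()].
#' @param baseline_window integer frame indices of the baseline.
#' @param background scalar background intensity (>= 0).
#' @return The trace with `F0`, `dff`, `baseline_window` populated.
#' @export
delta_f_over_f <- function(tr, baseline_window, background = 0) {
  stopifnot(inherits(tr, "sensor_trace"))
  if (length(baseline_window) == 0L) stop("baseline window is empty")
  if (any(baseline_window < 1L) || any(baseline_window > length(tr$t)))
    stop("baseline window outside the trace")
  if (background < 0) stop("background must be >= 0")
  Fb <- tr$F - background
  F0 <- mean(Fb[baseline_window])
  if (F0 <= 0) stop("F0 <= 0 after background subtraction")
  tr$F0 <- F0
  tr$dff <- (Fb - F0) / F0
  tr$baseline_window <- as.integer(baseline_window)
  tr
}

#' Hard low-pass Fourier filter
#'
#' Zeroes all frequency components strictly above `cutoff` Hz in the
#' discrete Fourier domain; DC (and hence the trace mean) is preserved
#' exactly and the filter is idempotent. Requires a uniform time base.
#'
#' @param tr a [sensor_trace()] (uniformly sampled).
#' @param cutoff cutoff frequency in Hz, `0 < cutoff < rate/2`.
#' @param rate sampling rate in Hz; inferred from `t` when `NULL`.
#' @param component `"F"` or `"dff"` — which series to filter.
#' @return The trace with the chosen series replaced by its filtered
#'   version.
#' @export
lowpass_fourier <- function(tr, cutoff, rate = NULL, component = c("F", "dff")) {
  component <- match.arg(component)
  stopifnot(inherits(tr, "sensor_trace"))
  dt <- diff(tr$t)
  if (max(dt) - min(dt) > 1e-6 * mean(dt)) stop("non-uniform time base")
  if (is.null(rate)) rate <- 1 / mean(dt)
  if (cutoff <= 0 || cutoff >= rate / 2)
    stop("cutoff must satisfy 0 < cutoff < rate/2")
  x <- if (component == "F") tr$F else {
    if (is.null(tr$dff)) stop("dff not computed") else tr$dff
  }
  n <- length(x)
  freq <- c(0, seq_len(n - 1)) ; freq <- pmin(freq, n - freq) * rate / n
  X <- stats::fft(x)
  X[freq > cutoff] <- 0
  y <- Re(stats::fft(X, inverse = TRUE)) / n
  if (component == "F") tr$F <- y else tr$dff <- y
  tr
}

#' Peak and mean response inside a stimulus window
#'
#' The maximum ("peak dF/F0 during photostimulation") and average
#' ("average dF/F0 during ligand stimulation") of the dF/F0 series over
#' the stimulus window.
#'
#' @param tr a [sensor_trace()] with `dff` computed.
#' @param stim_window integer frame indices of the stimulus period.
#' @return list: `peak_dff`, `mean_dff`.
#' @export
response_metrics <- function(tr, stim_window) {
  stopifnot(inherits(tr, "sensor_trace"))
  if (is.null(tr$dff)) stop("compute delta_f_over_f first")
  if (length(stim_window) == 0L) stop("empty stimulus window")
  if (any(stim_window < 1L) || any(stim_window > length(tr$t)))
    stop("stimulus window outside the trace")
  list(peak_dff = max(tr$dff[stim_window]), mean_dff = mean(tr$dff[stim_window]))
}

#' Fit a four-parameter Hill dose-response curve
#'
#' Least-squares fit of
#' `resp = bottom + (top - bottom) / (1 + (EC50 / conc)^hill)` with the
#' Hill slope free (optionally `bottom` fixed at 0). Fitting is performed
#' against log10 concentration internally for stability.
#'
#' @param conc molar concentrations (> 0), at least 4 spanning the
#'   transition.
#' @param resp responses (dF/F0).
#' @param fix_bottom_zero fix the lower asymptote at 0.
#' @return list of class `dose_response`: `conc`, `resp`, `fit` (EC50,
#'   hill, bottom, top), `residual_sd`.
#' @export
hill_fit <- function(conc, resp, fix_bottom_zero = FALSE) {
  if (length(conc) != length(resp)) stop("conc and resp must match")
  if (length(conc) < 4L) stop("need >= 4 concentrations")
  if (any(conc <= 0)) stop("concentrations must be > 0")
  o <- order(conc); conc <- conc[o]; resp <- resp[o]
  if (any(diff(resp) < -0.25 * max(abs(resp))))
    warning("responses are strongly non-monotone in concentration")
  lx <- log10(conc)
  bottom0 <- if (fix_bottom_zero) 0 else min(resp)
  top0 <- max(resp)
  half <- bottom0 + (top0 - bottom0) / 2
  ec0 <- 10^stats::approx(resp, lx, xout = half, ties = mean, rule = 2)$y
  # a start that coincides exactly with the optimum can make the final
  # model construction fail on noiseless data; retry from jittered starts
  try_fit <- function(jit) {
    if (fix_bottom_zero)
      minpack.lm::nlsLM(resp ~ top / (1 + 10^(hill * (lec - lx))),
                        start = list(top = top0 * (1 + jit),
                                     lec = log10(ec0) + jit, hill = 1),
                        control = minpack.lm::nls.lm.control(maxiter = 500))
    else
      minpack.lm::nlsLM(resp ~ bottom + (top - bottom) / (1 + 10^(hill * (lec - lx))),
                        start = list(bottom = bottom0, top = top0 * (1 + jit),
                                     lec = log10(ec0) + jit, hill = 1),
                        control = minpack.lm::nls.lm.control(maxiter = 500))
  }
  fit <- NULL
  for (jit in c(0, 0.05, -0.1, 0.2)) {
    fit <- tryCatch(try_fit(jit), error = function(e) NULL)
    if (!is.null(fit)) break
  }
  if (is.null(fit)) stop("Hill fit did not converge")
  cf <- stats::coef(fit)
  pars <- c(EC50 = 10^cf[["lec"]], hill = cf[["hill"]],
            bottom = if (fix_bottom_zero) 0 else cf[["bottom"]],
            top = cf[["top"]])
  structure(list(conc = conc, resp = resp, fit = pars,
                 residual_sd = stats::sd(stats::resid(fit))),
            class = "dose_response")
}

#' @export
print.dose_response <- function(x, ...) {
  cat(sprintf("dose_response: EC50 = %.3g M (%.3g nM), hill = %.3g, range [%.3g, %.3g]\n",
              x$fit["EC50"], x$fit["EC50"] * 1e9, x$fit["hill"],
              x$fit["bottom"], x$fit["top"]))
  invisible(x)
}

#' Single-exponential kinetics fit
#'
#' Fits `A * (1 - exp(-t/tau)) + C` (direction `"on"`) or
#' `A * exp(-t/tau) + C` (direction `"off"`) to a trace segment. Time is
#' re-referenced to the first sample. Warns when the trace covers less than
#' three fitted time constants.
#'
#' @param tr a [sensor_trace()] (fit uses `F`).
#' @param direction `"on"` or `"off"`.
#' @return list of class `kinetics_fit`: `tau` (s), `direction`,
#'   `amplitude`, `offset`, `residual_sd`.
#' @export
exp_kinetics_fit <- function(tr, direction = c("on", "off")) {
  direction <- match.arg(direction)
  stopifnot(inherits(tr, "sensor_trace"))
  tt <- tr$t - tr$t[1]
  y <- tr$F
  A0 <- max(y) - min(y)
  tau0 <- max(tt[length(tt)] / 5, diff(tt)[1])
  try_fit <- function(jit) {
    if (direction == "on")
      minpack.lm::nlsLM(y ~ A * (1 - exp(-tt / tau)) + C,
                        start = list(A = A0 * (1 + jit), tau = tau0 * (1 + jit), C = y[1]),
                        lower = c(A = -Inf, tau = 1e-9, C = -Inf),
                        control = minpack.lm::nls.lm.control(maxiter = 500))
    else
      minpack.lm::nlsLM(y ~ A * exp(-tt / tau) + C,
                        start = list(A = A0 * (1 + jit), tau = tau0 * (1 + jit),
                                     C = y[length(y)]),
                        lower = c(A = -Inf, tau = 1e-9, C = -Inf),
                        control = minpack.lm::nls.lm.control(maxiter = 500))
  }
  fit <- NULL
  for (jit in c(0, 0.1, -0.2, 0.5)) {  # retry from jittered starts (noiseless pathologies)
    fit <- tryCatch(try_fit(jit), error = function(e) NULL)
    if (!is.null(fit)) break
  }
  if (is.null(fit)) stop("exponential fit did not converge")
  cf <- stats::coef(fit)
  if (max(tt) < 3 * cf[["tau"]])
    warning(sprintf("trace covers only %.2g time constants (< 3)", max(tt) / cf[["tau"]]))
  structure(list(tau = cf[["tau"]], direction = direction,
                 amplitude = cf[["A"]], offset = cf[["C"]],
                 residual_sd = stats::sd(stats::resid(fit))),
            class = "kinetics_fit")
}

#' @export
print.kinetics_fit <- function(x, ...) {
  cat(sprintf("kinetics_fit: tau_%s = %.4g s\n", x$direction, x$tau))
  invisible(x)
}

#' Average frame pairs (temporal downsampling by 2)
#'
#' @param tr a [sensor_trace()].
#' @return A `trace` of half length (odd trailing frame dropped).
#' @export
temporal_average2 <- function(tr) {
  stopifnot(inherits(tr, "sensor_trace"))
  n <- 2L * (length(tr$t) %/% 2L)
  i1 <- seq(1L, n, by = 2L); i2 <- i1 + 1L
  sensor_trace((tr$t[i1] + tr$t[i2]) / 2, (tr$F[i1] + tr$F[i2]) / 2)
}

#' Mean intensity of a circular ROI on a projected frame series
#'
#' Extracts a trace as the mean intensity inside a disk of given radius
#' centred at caller-supplied (y, x) coordinates, one value per frame —
#' the 1-um-circle readout used at cilium-axon contact sites.
#'
#' @param frames 3D array (y, x, t) of projected frames.
#' @param center_yx numeric length-2 (y, x) in px.
#' @param radius_px disk radius in px.
#' @param t optional time stamps (defaults to frame index).
#' @return A [sensor_trace()].
#' @export
roi_trace <- function(frames, center_yx, radius_px, t = NULL) {
  d <- dim(frames)
  if (length(d) != 3L) stop("frames must be (y, x, t)")
  yy <- matrix(seq_len(d[1]), d[1], d[2])
  xx <- matrix(seq_len(d[2]), d[1], d[2], byrow = TRUE)
  disk <- (yy - center_yx[1])^2 + (xx - center_yx[2])^2 <= radius_px^2
  if (!any(disk)) stop("ROI contains no pixels")
  F <- vapply(seq_len(d[3]), function(k) mean(frames[, , k][disk]), numeric(1))
  sensor_trace(if (is.null(t)) seq_len(d[3]) else t, F)
}
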