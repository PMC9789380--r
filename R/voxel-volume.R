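#' Voxel volume with physical spacing
#'
#' The basic 3D container of the pipeline: a scalar field stored as an R
#' array indexed `[z, y, x]` together with the physical voxel size per axis
#' in micrometres (z, y, x order) and a free-text channel label. Physical
#' coordinates are voxel-centre positions, so voxel `(i, j, k)` (1-based)
#' sits at `((i - 0.5) * sz, (j - 0.5) * sy, (k - 0.5) * sx)` um.
#'
#' @param values numeric 3D array, dimensions `(nz, ny, nx)`; all finite.
#' @param spacing numeric length-3, voxel size in um per axis (z, y, x); all
#'   strictly positive. A single number is recycled (isotropic).
#' @param channel character label for the channel.
#' @param counts logical; if `TRUE` the volume holds photon counts and must
#'   be integer-valued and non-negative.
#' @return An object of class `voxel_volume`.
#' @export
voxel_volume <- function(values, spacing, channel = "", counts = FALSE) {
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("`values` must be a 3D array (z, y, x)")
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be 3 positive finite values (z, y, x) in um")
  if (any(!is.finite(values)))
    stop("volume values must all be finite")
  if (counts) {
    if (any(values < 0) || any(values != round(values)))
      stop("photon-count volumes must be integer-valued and >= 0")
  }
  structure(list(values = values, spacing = spacing,
                 channel = as.character(channel)[1L], counts = isTRUE(counts)),
            class = "voxel_volume")
}

#' @export
print.voxel_volume <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("voxel_volume '%s': %d x %d x %d (z,y,x), spacing %.4g x %.4g x %.4g um\n",
              x$channel, d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3]))
  cat(sprintf("  range [%.4g, %.4g]%s\n", min(x$values), max(x$values),
              if (x$counts) " (photon counts)" else ""))
  invisible(x)
}

#' @export
dim.voxel_volume <- function(x) dim(x$values)

is_isotropic <- function(vol, tol = 1e-6) {
  diff(range(vol$spacing)) <= tol * max(vol$spacing)
}

#' Multichannel volume on a shared grid
#'
#' A named collection of [voxel_volume()] objects sharing dimensions and
#' spacing. Channel names must be unique.
#'
#' @param channels named list of `voxel_volume` objects.
#' @return An object of class `multichannel_volume`.
#' @export
multichannel_volume <- function(channels) {
  if (length(channels) == 0L) stop("at least one channel required")
  nm <- names(channels)
  if (is.null(nm) || any(nm == "") || anyDuplicated(nm))
    stop("channels must have unique non-empty names")
  if (!all(vapply(channels, inherits, logical(1), "voxel_volume")))
    stop("all channels must be voxel_volume objects")
  d0 <- dim(channels[[1L]]$values); s0 <- channels[[1L]]$spacing
  for (ch in channels[-1L]) {
    if (!identical(dim(ch$values), d0) || max(abs(ch$spacing - s0)) > 1e-9)
      stop("all channels must share dimensions and spacing")
  }
  structure(list(channels = channels), class = "multichannel_volume")
}

#' @export
print.multichannel_volume <- function(x, ...) {
  d <- dim(x$channels[[1L]]$values)
  cat(sprintf("multichannel_volume: %d channel(s) [%s], %d x %d x %d (z,y,x)\n",
              length(x$channels), paste(names(x$channels), collapse = ", "),
              d[1], d[2], d[3]))
  invisible(x)
}

#' FLIM volume: photon counts paired with lifetimes
#'
#' Two aligned scalar fields as exported by lifetime-imaging software: one
#' channel encodes per-voxel photon counts, the other the per-voxel mean
#' photon arrival time (or fitted lifetime) in ns. Arrival must be finite
#' and non-negative wherever counts are positive.
#'
#' @param counts non-negative integer 3D array of photon counts.
#' @param arrival numeric 3D array of arrival times / lifetimes in ns.
#' @param spacing voxel size in um (z, y, x) or a scalar.
#' @return An object of class `flim_volume`.
#' @export
flim_volume <- function(counts, arrival, spacing = 1) {
  if (!identical(dim(counts), dim(arrival)))
    stop("counts and arrival must have identical dimensions")
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be integer-valued and >= 0")
  pos <- counts > 0
  if (any(!is.finite(arrival[pos])) || any(arrival[pos] < 0))
    stop("arrival must be finite and >= 0 wherever counts > 0")
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  structure(list(counts = counts, arrival = arrival, spacing = as.numeric(spacing)),
            class = "flim_volume")
}

#' @export
print.flim_volume <- function(x, ...) {
  d <- dim(x$counts)
  cat(sprintf("flim_volume: %d x %d x %d (z,y,x), total %d photons, arrival range [%.3g, %.3g] ns\n",
              d[1], d[2], d[3], sum(x$counts),
              min(x$arrival[x$counts > 0]), max(x$arrival[x$counts > 0])))
  invisible(x)
}

#' Spectral mixing matrix
#'
#' Detection-channels x fluorophores coefficient matrix used by
#' [linear_unmix()]. Must be square or overdetermined (rows >= columns),
#' non-negative, and well conditioned.
#'
#' @param m numeric matrix of non-negative coefficients.
#' @param max_condition largest acceptable condition number.
#' @return An object of class `mixing_matrix`.
#' @export
mixing_matrix <- function(m, max_condition = 1e8) {
  m <- as.matrix(m)
  if (nrow(m) < ncol(m)) stop("mixing matrix must be square or overdetermined")
  if (any(m < 0)) stop("mixing coefficients must be >= 0")
  k <- kappa(m, exact = TRUE)
  if (!is.finite(k) || k > max_condition)
    stop(sprintf("mixing matrix is ill conditioned (condition number %.3g)", k))
  structure(list(matrix = m, condition = k), class = "mixing_matrix")
}

#' Resample a volume to isotropic voxels
#'
#' Trilinear (or nearest-neighbour) interpolation onto an isotropic grid of
#' voxel size `target` um, preserving physical extent to within one voxel
#' per axis. Downsampling to the coarsest acquisition axis is the standard
#' preparation step before skeletonization and distance mapping.
#'
#' @param vol a [voxel_volume()].
#' @param target isotropic voxel size in um, > 0.
#' @param method `"linear"` for intensities, `"nearest"` for masks/labels.
#' @param downsample_only if `TRUE`, require `target >= max(spacing)`.
#' @return A `voxel_volume` with spacing `c(target, target, target)`.
#' @export
resample_isotropic <- function(vol, target, method = c("linear", "nearest"),
                               downsample_only = FALSE) {
  method <- match.arg(method)
  stopifnot(inherits(vol, "voxel_volume"))
  if (!is.finite(target) || target <= 0) stop("`target` must be a positive number")
  if (downsample_only && target < max(vol$spacing) - 1e-12)
    stop("target is finer than the coarsest axis but downsample_only = TRUE")
  d <- dim(vol$values)
  if (any(d == 0L)) stop("empty volume")
  extent <- d * vol$spacing
  nd <- pmax(1L, as.integer(round(extent / target)))
  if (identical(as.integer(d), nd) && max(abs(vol$spacing - target)) < 1e-12)
    return(vol)
  # voxel-centre coordinates of the new grid, expressed in old voxel index units
  idx <- lapply(1:3, function(a) {
    pos <- (seq_len(nd[a]) - 0.5) * target        # physical um
    old <- pos / vol$spacing[a] + 0.5             # 1-based fractional old index
    pmin(pmax(old, 1), d[a])
  })
  out <- interp3(vol$values, idx[[1L]], idx[[2L]], idx[[3L]], method)
  voxel_volume(out, target, channel = vol$channel)
}

# trilinear / nearest interpolation of arr at the tensor grid (zi, yi, xi),
# fractional 1-based indices already clamped to bounds
interp3 <- function(arr, zi, yi, xi, method = "linear") {
  d <- dim(arr)
  nz <- length(zi); ny <- length(yi); nx <- length(xi)
  if (method == "nearest") {
    z0 <- pmin(pmax(round(zi), 1), d[1])
    y0 <- pmin(pmax(round(yi), 1), d[2])
    x0 <- pmin(pmax(round(xi), 1), d[3])
    lin <- as.vector(outer(outer(z0, (y0 - 1) * d[1], "+"), (x0 - 1) * d[1] * d[2], "+"))
    return(array(arr[lin], c(nz, ny, nx)))
  }
  lo <- function(v, n) pmin(pmax(floor(v), 1), n - if (n > 1) 1 else 0)
  z0 <- lo(zi, d[1]); y0 <- lo(yi, d[2]); x0 <- lo(xi, d[3])
  fz <- zi - z0; fy <- yi - y0; fx <- xi - x0
  z1 <- pmin(z0 + 1, d[1]); y1 <- pmin(y0 + 1, d[2]); x1 <- pmin(x0 + 1, d[3])
  get <- function(a, b, cc) {
    arr[as.vector(outer(outer(a, (b - 1) * d[1], "+"), (cc - 1) * d[1] * d[2], "+"))]
  }
  wz <- array(rep(fz, ny * nx), c(nz, ny, nx))
  wy <- array(rep(rep(fy, each = nz), nx), c(nz, ny, nx))
  wx <- array(rep(fx, each = nz * ny), c(nz, ny, nx))
  v000 <- get(z0, y0, x0); v100 <- get(z1, y0, x0)
  v010 <- get(z0, y1, x0); v110 <- get(z1, y1, x0)
  v001 <- get(z0, y0, x1); v101 <- get(z1, y0, x1)
  v011 <- get(z0, y1, x1); v111 <- get(z1, y1, x1)
  out <- (1 - wz) * (1 - wy) * (1 - wx) * v000 + wz * (1 - wy) * (1 - wx) * v100 +
         (1 - wz) * wy * (1 - wx) * v010 + wz * wy * (1 - wx) * v110 +
         (1 - wz) * (1 - wy) * wx * v001 + wz * (1 - wy) * wx * v101 +
         (1 - wz) * wy * wx * v011 + wz * wy * wx * v111
  array(out, c(nz, ny, nx))
}

#' Linear spectral unmixing
#'
#' Recovers per-voxel fluorophore abundances from multi-detector data by
#' solving the linear mixing model in the least-squares sense, voxel by
#' voxel. Negative least-squares solutions are resolved by a small
#' active-set non-negative fit, so abundances are physical (>= 0); the
#' number of clipped voxels is reported via a warning-level message.
#'
#' @param mc a [multichannel_volume()] of detector channels (order must match
#'   the rows of `mix`).
#' @param mix a [mixing_matrix()] with one column per fluorophore.
#' @param fluorophores optional character names for the output channels.
#' @return A `multichannel_volume` of abundance channels.
#' @export
linear_unmix <- function(mc, mix, fluorophores = NULL) {
  stopifnot(inherits(mc, "multichannel_volume"), inherits(mix, "mixing_matrix"))
  M <- mix$matrix
  if (length(mc$channels) != nrow(M))
    stop(sprintf("channel count (%d) does not match mixing-matrix rows (%d)",
                 length(mc$channels), nrow(M)))
  d <- dim(mc$channels[[1L]]$values)
  nvox <- prod(d)
  Y <- vapply(mc$channels, function(ch) as.vector(ch$values), numeric(nvox))
  Y <- t(Y)                                     # channels x voxels
  A <- qr.solve(M, Y)                           # unconstrained LS, all voxels at once
  neg <- which(apply(A < -1e-12, 2L, any))
  if (length(neg)) {
    for (j in neg) A[, j] <- nnls_small(M, Y[, j, drop = TRUE])
    message(sprintf("linear_unmix: %d voxel(s) required non-negative clipping", length(neg)))
  }
  A[A < 0] <- 0
  sp <- mc$channels[[1L]]$spacing
  if (is.null(fluorophores)) fluorophores <- paste0("fluor", seq_len(ncol(M)))
  out <- lapply(seq_len(ncol(M)), function(k)
    voxel_volume(array(A[k, ], d), sp, channel = fluorophores[k]))
  names(out) <- fluorophores
  multichannel_volume(out)
}

# active-set non-negative least squares for small systems (Lawson-Hanson)
nnls_small <- function(A, b, tol = 1e-10) {
  n <- ncol(A)
  x <- numeric(n)
  passive <- logical(n)
  w <- crossprod(A, b - A %*% x)
  iter <- 0L
  while (any(!passive & w > tol) && iter < 30L * n) {
    iter <- iter + 1L
    j <- which.max(ifelse(passive, -Inf, w))
    passive[j] <- TRUE
    repeat {
      s <- numeric(n)
      s[passive] <- qr.solve(A[, passive, drop = FALSE], b)
      if (all(s[passive] > tol)) { x <- s; break }
      neg <- passive & s <= tol
      alpha <- min(x[neg] / (x[neg] - s[neg]))
      x <- x + alpha * (s - x)
      passive[passive & x <= tol] <- FALSE
      x[!passive] <- 0
    }
    w <- crossprod(A, b - A %*% x)
  }
  x
}

#' Split a FLIM volume into signal and background by arrival-time gate
#'
#' Photon-arrival-time gating separates a fast autofluorescence background
#' population (peaking near 0.3 ns) from slow dye signal (peaking near
#' 2.3 ns): voxels whose mean arrival time is at or above the gate
#' contribute their counts to the signal channel, all others to the
#' background channel. Counts are conserved exactly.
#'
#' @param fv a [flim_volume()].
#' @param gate gate in ns (> 0); default 1.0 ns sits between the two
#'   population peaks.
#' @return list with `voxel_volume` elements `signal` and `background`.
#' @export
flim_split <- function(fv, gate = 1.0) {
  stopifnot(inherits(fv, "flim_volume"))
  if (!is.finite(gate) || gate <= 0) stop("`gate` must be a positive finite ns value")
  sel <- fv$arrival >= gate & fv$counts > 0
  sig <- fv$counts; sig[!sel] <- 0
  bg <- fv$counts - sig
  list(signal = voxel_volume(sig, fv$spacing, channel = "signal", counts = TRUE),
       background = voxel_volume(bg, fv$spacing, channel = "background", counts = TRUE))
}
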