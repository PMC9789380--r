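#' Binary mask on a physical grid
#'
#' Logical 3D field with the same grid contract as [voxel_volume()].
#'
#' @param values logical 3D array (z, y, x).
#' @param spacing voxel size in um (z, y, x) or a scalar.
#' @return An object of class `binary_mask`.
#' @export
binary_mask <- function(values, spacing) {
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("`values` must be a 3D array")
  storage.mode(values) <- "logical"
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  spacing <- as.numeric(spacing)
  if (any(spacing <= 0)) stop("spacing must be positive")
  structure(list(values = values, spacing = spacing), class = "binary_mask")
}

#' @export
print.binary_mask <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("binary_mask: %d x %d x %d (z,y,x), %d foreground voxel(s)\n",
              d[1], d[2], d[3], sum(x$values)))
  invisible(x)
}

#' Euclidean distance transform to a target mask
#'
#' Exact Euclidean distance (in um) from every voxel to the nearest `TRUE`
#' voxel of `mask`, honouring anisotropic spacing. An empty target yields
#' `+Inf` everywhere.
#'
#' @param mask a [binary_mask()] (distances measured TO its foreground).
#' @return numeric 3D array of distances in um.
#' @export
distance_to <- function(mask) {
  stopifnot(inherits(mask, "binary_mask"))
  d <- dim(mask$values)
  array(edt3d_cpp(as.vector(mask$values), as.integer(d), mask$spacing), d)
}

#' Connected-component labelling
#'
#' @param mask a [binary_mask()].
#' @param connectivity 6 or 26.
#' @return integer 3D array of labels (0 = background).
#' @export
label_components <- function(mask, connectivity = 26L) {
  stopifnot(inherits(mask, "binary_mask"), connectivity %in% c(6L, 26L))
  d <- dim(mask$values)
  array(label3d_cpp(as.vector(mask$values), as.integer(d), as.integer(connectivity)), d)
}

# Euclidean-ball dilation/erosion: for small radii an explicit voxel-offset
# structuring element; for large radii the distance-transform formulation
# (dilation = within r um of foreground, erosion = farther than r um from
# background). Both are exact for Euclidean balls.
ball_offsets <- function(radius_um, spacing) {
  rv <- floor(radius_um / spacing)
  g <- as.matrix(expand.grid(dz = -rv[1]:rv[1], dy = -rv[2]:rv[2], dx = -rv[3]:rv[3]))
  keep <- (g[, 1] * spacing[1])^2 + (g[, 2] * spacing[2])^2 +
    (g[, 3] * spacing[3])^2 <= (radius_um + 1e-9)^2
  g[keep, , drop = FALSE]
}

dilate_ball <- function(mask, radius_um) {
  if (radius_um <= 0) return(mask)
  if (radius_um / min(mask$spacing) <= 4) {
    off <- ball_offsets(radius_um, mask$spacing)
    d <- dim(mask$values)
    return(binary_mask(array(morph3d_cpp(as.vector(mask$values), as.integer(d),
                                         off, TRUE), d), mask$spacing))
  }
  binary_mask(distance_to(mask) <= radius_um + 1e-9, mask$spacing)
}

erode_ball <- function(mask, radius_um) {
  if (radius_um <= 0) return(mask)
  if (radius_um / min(mask$spacing) <= 4) {
    off <- ball_offsets(radius_um, mask$spacing)
    d <- dim(mask$values)
    return(binary_mask(array(morph3d_cpp(as.vector(mask$values), as.integer(d),
                                         off, FALSE), d), mask$spacing))
  }
  inv <- binary_mask(!mask$values, mask$spacing)
  binary_mask(distance_to(inv) > radius_um + 1e-9, mask$spacing)
}

# separable Gaussian smoothing of a 3D array, sigma per axis in voxels
gauss3 <- function(arr, sigma) {
  if (length(sigma) == 1L) sigma <- rep(sigma, 3L)
  d <- dim(arr)
  for (ax in 1:3) {
    s <- sigma[ax]
    if (s <= 0) next
    r <- max(1L, ceiling(3 * s))
    k <- stats::dnorm(-r:r, sd = s); k <- k / sum(k)
    arr <- conv_axis(arr, k, ax)
  }
  arr
}

# 1D convolution of a 3D array along an axis with replicate padding
conv_axis <- function(arr, k, axis) {
  d <- dim(arr)
  array(conv_axis_cpp(as.vector(arr), as.integer(d), k, axis), d)
}

# 2D separable Gaussian smoothing with replicate padding
gauss2 <- function(m, sigma) {
  if (sigma <= 0) return(m)
  r <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-r:r, sd = sigma); k <- k / sum(k)
  conv_rows <- function(mm) {
    pad <- rbind(mm[rep(1L, r), , drop = FALSE], mm, mm[rep(nrow(mm), r), , drop = FALSE])
    out <- matrix(0, nrow(mm), ncol(mm))
    for (i in seq_along(k)) out <- out + k[i] * pad[i:(i + nrow(mm) - 1L), , drop = FALSE]
    out
  }
  t(conv_rows(t(conv_rows(m))))
}
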