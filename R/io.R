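#' Write a volume as multi-page TIFF with a JSON metadata sidecar
#'
#' One TIFF page per z plane (32-bit float), plus `<path>.json` carrying the
#' voxel spacing in um, the channel label, and the intensity scale. The
#' sidecar is the authoritative source of spacing on read; volumes without
#' spacing metadata are refused rather than silently defaulted.
#'
#' @param vol a [voxel_volume()].
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "voxel_volume"))
  d <- dim(vol$values)
  rng <- range(vol$values)
  scale <- if (rng[2] > 0) rng[2] else 1
  pages <- lapply(seq_len(d[1]), function(z)
    matrix(vol$values[z, , ] / scale, d[2], d[3]))
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  meta <- list(spacing_um = vol$spacing, channel = vol$channel,
               intensity_scale = scale, counts = vol$counts, axes = "ZYX")
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a volume written by [write_volume()]
#'
#' @param path TIFF path; `<path>.json` must exist and contain `spacing_um`.
#' @return A [voxel_volume()].
#' @export
read_volume <- function(path) {
  side <- paste0(path, ".json")
  if (!file.exists(side))
    stop("missing metadata sidecar '", side, "': voxel spacing is required, not defaulted")
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  if (is.null(meta$spacing_um) || length(meta$spacing_um) != 3L)
    stop("sidecar must provide spacing_um as (z, y, x) in um")
  pages <- tiff::readTIFF(path, all = TRUE)
  if (is.matrix(pages)) pages <- list(pages)
  d <- c(length(pages), nrow(pages[[1L]]), ncol(pages[[1L]]))
  arr <- array(0, d)
  for (z in seq_len(d[1])) arr[z, , ] <- pages[[z]]
  scale <- if (is.null(meta$intensity_scale)) 1 else meta$intensity_scale
  arr <- arr * scale
  cnt <- isTRUE(meta$counts)
  if (cnt) arr <- round(arr)
  voxel_volume(arr, meta$spacing_um,
               channel = if (is.null(meta$channel)) "" else meta$channel,
               counts = cnt)
}

#' Write / read a binary mask as 8-bit TIFF with sidecar
#' @param mask a [binary_mask()].
#' @param path TIFF path.
#' @return `path` invisibly (write); a `binary_mask` (read).
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "binary_mask"))
  v <- voxel_volume(array(as.numeric(mask$values), dim(mask$values)),
                    mask$spacing, channel = "mask")
  write_volume(v, path)
}

#' @rdname write_mask
#' @export
read_mask <- function(path) {
  v <- read_volume(path)
  binary_mask(v$values > 0.5, v$spacing)
}
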