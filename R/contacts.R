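#' Contact-analysis parameters
#'
#' Cutoffs for the axo-ciliary proximity analysis. The 2-um axon-contact
#' cutoff reflects the 1-3 um size of serotonergic varicosities; puncta
#' within 1 um of an axon central axis are considered axon-associated.
#' Both comparisons are inclusive (<=).
#'
#' @param contact_cutoff cilium-axon skeleton distance cutoff in um.
#' @param puncta_axon_cutoff punctum-axon skeleton distance cutoff in um.
#' @param boundary_margin margin in voxels for boundary exclusion.
#' @return An object of class `contact_params`.
#' @export
contact_params <- function(contact_cutoff = 2.0, puncta_axon_cutoff = 1.0,
                           boundary_margin = 1L) {
  stopifnot(contact_cutoff > 0, puncta_axon_cutoff > 0, boundary_margin >= 0)
  structure(list(contact_cutoff = contact_cutoff,
                 puncta_axon_cutoff = puncta_axon_cutoff,
                 boundary_margin = as.integer(boundary_margin)),
            class = "contact_params")
}

#' Exclude invalid cilia (volume boundary, non-layer nuclei)
#'
#' Builds the per-cilium table and flags exclusions: a cilium is excluded
#' when any skeleton voxel lies within `boundary_margin` voxels of a volume
#' face, or when its nearest nucleus centre (to the cilium base, i.e. the
#' skeleton voxel closest to any nucleus centre) falls outside the cell
#' layer mask.
#'
#' @param skels a [skeleton_set()] of cilia.
#' @param layer a [binary_mask()] of the selected cell layer (same grid).
#' @param centers nucleus centres as returned by [nucleus_centers()]
#'   (matrix, columns z, y, x in um); may have zero rows.
#' @param params a [contact_params()].
#' @return A `cilium_table` data.frame: id, length_um, min_axon_distance,
#'   min_nucleus_distance, contacting, excluded, exclusion_reason.
#' @export
filter_cilia <- function(skels, layer, centers, params = contact_params()) {
  stopifnot(inherits(skels, "skeleton_set"), inherits(layer, "binary_mask"))
  if (any(skels$dim != dim(layer$values)))
    stop("skeleton and layer must be on the same grid")
  n <- length(skels$instances)
  m <- params$boundary_margin
  d <- skels$dim
  tab <- data.frame(id = seq_len(n),
                    length_um = NA_real_,
                    min_axon_distance = NA_real_,
                    min_nucleus_distance = NA_real_,
                    contacting = NA,
                    excluded = FALSE,
                    exclusion_reason = "none",
                    stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    vox <- skels$instances[[i]]
    tab$length_um[i] <- cilium_length(vox, skels$spacing, radius = skels$radius[[i]],
                                      mask = skels$mask)
    if (any(vox <= m) || any(sweep(vox, 2L, d - m, ">"))) {
      tab$excluded[i] <- TRUE
      tab$exclusion_reason[i] <- "boundary"
      next
    }
    if (nrow(centers) > 0L) {
      co <- skels$coords[[i]]
      dd <- outer(rowSums(co^2), rowSums(centers^2), "+") - 2 * co %*% t(centers)
      dd[dd < 0] <- 0
      tab$min_nucleus_distance[i] <- sqrt(min(dd))
      nuc <- arrayInd(which.min(dd), dim(dd))[, 2]
      nv <- pmin(pmax(ceiling(centers[nuc, ] / layer$spacing), 1L), d)
      if (!layer$values[nv[1], nv[2], nv[3]]) {
        tab$excluded[i] <- TRUE
        tab$exclusion_reason[i] <- "non_layer_nucleus"
      }
    }
  }
  class(tab) <- c("cilium_table", "data.frame")
  tab
}

#' Distance from cilium skeleton voxels to a target structure
#'
#' The 3D Euclidean distance transform of the target is sampled at every
#' cilium skeleton voxel ("distance-encoded central axis"), and the
#' per-cilium minimum is recorded. An empty target yields +Inf distances
#' with a warning.
#'
#' @param cilia a [skeleton_set()].
#' @param target a [binary_mask()] or `skeleton_set` (rasterized) on the
#'   same grid.
#' @return list: `per_voxel` (list of per-instance distance vectors, um),
#'   `minima` (per-cilium minimum, um).
#' @export
distance_on_skeleton <- function(cilia, target, refine = FALSE) {
  stopifnot(inherits(cilia, "skeleton_set"))
  tm <- if (inherits(target, "skeleton_set")) skeleton_to_mask(target) else target
  stopifnot(inherits(tm, "binary_mask"))
  if (any(cilia$dim != dim(tm$values)))
    stop("cilia and target must share a grid")
  if (!any(tm$values)) {
    warning("empty target: distances are +Inf")
    pv <- lapply(cilia$instances, function(m) rep(Inf, nrow(m)))
    return(list(per_voxel = pv, minima = rep(Inf, length(pv))))
  }
  dt <- distance_to(tm)
  pv <- lapply(cilia$instances, function(m) dt[m])
  minima <- vapply(pv, min, numeric(1))
  if (refine && inherits(target, "skeleton_set")) {
    # sub-voxel refinement: minimum point-to-point distance between the
    # re-centred skeleton voxels of cilia and target, which removes the
    # half-voxel jitter of the digital skeletons from the per-cilium minima
    cp <- lapply(seq_along(cilia$instances), function(i) refined_axis_points(cilia, i))
    tp <- do.call(rbind, lapply(seq_along(target$instances),
                                function(i) refined_axis_points(target, i)))
    minima <- vapply(cp, function(p) polyline_dist(p, tp), numeric(1))
  }
  list(per_voxel = pv, minima = minima)
}

#' Rasterize a skeleton set back to a binary mask
#' @param skels a [skeleton_set()].
#' @return A [binary_mask()].
#' @export
skeleton_to_mask <- function(skels) {
  arr <- array(FALSE, skels$dim)
  for (m in skels$instances) arr[m] <- TRUE
  binary_mask(arr, skels$spacing)
}

#' Classify axon-contacting cilia
#'
#' Sets `contacting = (min_axon_distance <= contact_cutoff)` for every
#' non-excluded cilium (inclusive comparison; a cilium at exactly the
#' cutoff counts as contacting).
#'
#' @param table a `cilium_table` with `min_axon_distance` populated.
#' @param params a [contact_params()].
#' @return The table with `contacting` filled in.
#' @export
classify_contacts <- function(table, params = contact_params()) {
  if (any(is.na(table$min_axon_distance[!table$excluded])))
    stop("min_axon_distance must be populated before classification")
  keep <- !table$excluded
  table$contacting[keep] <- table$min_axon_distance[keep] <= params$contact_cutoff + 1e-9
  table$contacting[!keep] <- NA
  table
}

#' Associate puncta with axons by skeleton distance
#'
#' Labels each punctum associated when its Euclidean distance to the
#' nearest axon-skeleton voxel centre is at most `puncta_axon_cutoff` um.
#' An empty skeleton leaves all puncta unassociated.
#'
#' @param puncta a [puncta_set()].
#' @param axon_skel a [skeleton_set()] of axons.
#' @param params a [contact_params()].
#' @return The `puncta_set` with `association` and `axon_distance` filled.
#' @export
associate_puncta <- function(puncta, axon_skel, params = contact_params()) {
  stopifnot(inherits(puncta, "puncta_set"), inherits(axon_skel, "skeleton_set"))
  np <- nrow(puncta$centroids)
  sk <- do.call(rbind, axon_skel$coords)
  if (is.null(sk) || nrow(sk) == 0L || np == 0L) {
    puncta$association <- rep(FALSE, np)
    puncta$axon_distance <- rep(Inf, np)
    return(puncta)
  }
  dd <- outer(rowSums(puncta$centroids^2), rowSums(sk^2), "+") -
    2 * puncta$centroids %*% t(sk)
  dd[dd < 0] <- 0
  dmin <- sqrt(apply(dd, 1L, min))
  puncta$axon_distance <- dmin
  puncta$association <- dmin <= params$puncta_axon_cutoff + 1e-9
  puncta
}

#' Rounded percentage of a count
#'
#' `round(100 * count / total)` to the nearest integer (half away from
#' zero), the convention used for headline contact rates such as
#' 426/1209 -> 35 and 18/27 -> 67.
#'
#' @param count integer, `0 <= count <= total`.
#' @param total positive integer.
#' @return integer percent.
#' @export
percent_of <- function(count, total) {
  if (total <= 0) stop("total must be > 0")
  if (count < 0 || count > total) stop("count must be in [0, total]")
  as.integer(floor(100 * count / total + 0.5))
}

#' Fraction of receptor signal inside the ciliary compartment
#'
#' Integrated receptor intensity inside the 1-voxel-dilated cilia mask
#' divided by the integrated receptor intensity over all voxels at or above
#' `total_threshold` (photon counts). Computed on a shared isotropic grid.
#'
#' @param receptor a [voxel_volume()] of receptor signal.
#' @param cilia_mask a [binary_mask()] of cilia (same grid).
#' @param dilate_px mask dilation in voxels (default 1).
#' @param total_threshold count cutoff defining "total" signal (default 20).
#' @return fraction in `[0, 1]` (clamped at 1 when the dilated mask captures
#'   sub-threshold signal).
#' @export
ciliary_fraction <- function(receptor, cilia_mask, dilate_px = 1L, total_threshold = 20) {
  stopifnot(inherits(receptor, "voxel_volume"), inherits(cilia_mask, "binary_mask"))
  if (!identical(dim(receptor$values), dim(cilia_mask$values)))
    stop("receptor and cilia mask must share a grid")
  dil <- dilate_ball(cilia_mask, dilate_px * max(cilia_mask$spacing))
  total <- sum(receptor$values[receptor$values >= total_threshold])
  if (total <= 0) stop("zero total receptor intensity above threshold")
  min(sum(receptor$values[dil$values]) / total, 1)
}

#' Summary counts for a cilium table
#'
#' @param table a `cilium_table` after [classify_contacts()].
#' @return list: n_total, n_excluded, n_analyzed, n_contacting,
#'   percent_contacting (rounded percent of analyzed cilia).
#' @export
contact_summary <- function(table) {
  keep <- !table$excluded
  n_c <- sum(table$contacting[keep], na.rm = TRUE)
  list(n_total = nrow(table),
       n_excluded = sum(table$excluded),
       n_analyzed = sum(keep),
       n_contacting = n_c,
       percent_contacting = if (sum(keep) > 0) percent_of(n_c, sum(keep)) else NA_integer_)
}

#' @export
print.cilium_table <- function(x, ...) {
  s <- contact_summary(x)
  cat(sprintf("cilium_table: %d cilia (%d excluded); %d/%d contacting (%s%%)\n",
              s$n_total, s$n_excluded, s$n_contacting, s$n_analyzed,
              ifelse(is.na(s$percent_contacting), "NA", s$percent_contacting)))
  NextMethod()
}
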