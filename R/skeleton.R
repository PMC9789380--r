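#' Skeletonize a mask into per-instance central axes
#'
#' 3D topological thinning (distance-ordered homotopic thinning with a
#' (26,6) simple-point test) reduces each tubular structure to a one-voxel
#' curve skeleton; connected skeleton components define the instances,
#' which also serves to separate and identify distinct cilia. Spurious side
#' branches shorter than `prune_below` voxels are pruned.
#'
#' @param mask a [binary_mask()] on an isotropic grid (resample first).
#' @param prune_below prune leaf branches with fewer than this many voxels
#'   (default 3); set 0 to disable.
#' @return An object of class `skeleton_set`: list with `instances` (each a
#'   matrix of 1-based voxel indices, columns z, y, x), `coords` (physical
#'   um coordinates per instance), `spacing`, `dim`.
#' @export
skeletonize_instances <- function(mask, prune_below = 3L) {
  stopifnot(inherits(mask, "binary_mask"))
  sp <- mask$spacing
  if (diff(range(sp)) > 1e-6 * max(sp))
    stop("skeletonize_instances requires isotropic spacing; run resample_isotropic() first")
  d <- dim(mask$values)
  # protect each component's geodesically-farthest voxel pair (cap tips)
  # so thinning cannot retreat off the tube ends
  anch <- cap_anchors_cpp(as.vector(mask$values), as.integer(d))
  sk <- array(thin3d_cpp(as.vector(mask$values), as.integer(d), anch), d)
  if (prune_below > 0L) sk <- prune_skeleton(sk, prune_below)
  lab <- array(label3d_cpp(as.vector(sk), as.integer(d), 26L), d)
  n <- max(lab)
  instances <- vector("list", n)
  if (n > 0L) {
    idx <- which(lab > 0L, arr.ind = TRUE)
    lv <- lab[lab > 0L]
    for (l in seq_len(n)) {
      m <- idx[lv == l, , drop = FALSE]
      colnames(m) <- c("z", "y", "x")
      instances[[l]] <- m
    }
  }
  coords <- lapply(instances, function(m) sweep(m - 0.5, 2L, sp, "*"))
  # local tube radius at each skeleton voxel (distance to background):
  # used to compensate endpoint retreat when measuring lengths
  rad <- array(edt3d_cpp(as.vector(!mask$values), as.integer(d), sp), d)
  radius <- lapply(instances, function(m) rad[m])
  structure(list(instances = instances, coords = coords, radius = radius,
                 mask = mask$values, spacing = sp, dim = d),
            class = "skeleton_set")
}

#' @export
print.skeleton_set <- function(x, ...) {
  cat(sprintf("skeleton_set: %d instance(s), %d voxel(s) total\n",
              length(x$instances), sum(vapply(x$instances, nrow, integer(1)))))
  invisible(x)
}

# remove leaf branches shorter than min_vox voxels (measured to the first
# junction); repeated once per call, which removes thinning artefacts
prune_skeleton <- function(sk, min_vox) {
  idx <- which(sk, arr.ind = TRUE)
  if (nrow(idx) < 2L) return(sk)
  g <- skeleton_graph(idx)
  deg <- igraph::degree(g)
  leaves <- which(deg == 1L)
  drop <- integer(0)
  for (lf in leaves) {
    path <- lf
    cur <- lf; prev <- -1L
    repeat {
      nbs <- as.integer(igraph::neighbors(g, cur))
      nxt <- setdiff(nbs, prev)
      if (length(nxt) != 1L) break          # junction or isolated end
      if (deg[nxt] >= 3L) { break }          # stop at junction, don't include it
      prev <- cur; cur <- nxt
      path <- c(path, cur)
      if (length(path) >= min_vox) break
    }
    # prune only genuine side branches: last node must neighbour a junction
    end_nbs <- as.integer(igraph::neighbors(g, cur))
    if (length(path) < min_vox && any(deg[end_nbs] >= 3L))
      drop <- c(drop, path)
  }
  if (length(drop)) {
    rm_idx <- idx[unique(drop), , drop = FALSE]
    sk[rm_idx] <- FALSE
  }
  sk
}

# igraph over skeleton voxels, 26-neighbour edges, weight = physical step
skeleton_graph <- function(idx, spacing = c(1, 1, 1)) {
  n <- nrow(idx)
  key <- paste(idx[, 1], idx[, 2], idx[, 3])
  lookup <- seq_len(n)
  names(lookup) <- key
  from <- integer(0); to <- integer(0); w <- numeric(0)
  offs <- as.matrix(expand.grid(dz = -1:1, dy = -1:1, dx = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  offs <- offs[offs[, 1] > 0 | (offs[, 1] == 0 & offs[, 2] > 0) |
                 (offs[, 1] == 0 & offs[, 2] == 0 & offs[, 3] > 0), , drop = FALSE]
  for (k in seq_len(nrow(offs))) {
    nb <- sweep(idx, 2L, offs[k, ], "+")
    nbk <- paste(nb[, 1], nb[, 2], nb[, 3])
    hit <- lookup[nbk]
    ok <- !is.na(hit)
    if (any(ok)) {
      from <- c(from, lookup[key[ok]])
      to <- c(to, hit[ok])
      w <- c(w, rep(sqrt(sum((offs[k, ] * spacing)^2)), sum(ok)))
    }
  }
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (length(from)) g <- igraph::add_edges(g, rbind(from, to), weight = w)
  g
}

#' Physical length of a skeleton instance
#'
#' Length along the longest geodesic path through the skeleton graph
#' (26-connectivity steps weighted by their physical step length; for
#' branched skeletons, the longest end-to-end path). The raw digital path
#' both zigzags (overestimating oblique curves by up to ~10%) and runs cap
#' tip to cap tip (overshooting each end by about one tube radius), so the
#' estimator optionally (a) re-centres each path vertex on the tube
#' cross-section centroid (sub-voxel, perpendicular to the local tangent)
#' when the source `mask` is available, (b) applies a symmetric moving
#' average that pins the endpoints, and (c) trims the per-end cap
#' overshoot using the local tube `radius`.
#'
#' @param instance matrix of voxel indices (columns z, y, x) as produced by
#'   [skeletonize_instances()].
#' @param spacing isotropic voxel size in um (scalar or length 3).
#' @param smooth_window moving-average window (voxels, odd; 1 disables).
#' @param radius per-voxel local tube radii (um) as stored in
#'   `skeleton_set$radius`; enables the end correction.
#' @param mask logical 3D array of the source mask; enables sub-voxel
#'   re-centring.
#' @return length in um (0 for a single-voxel instance).
#' @export
cilium_length <- function(instance, spacing, smooth_window = 3L, radius = NULL,
                          mask = NULL) {
  if (is.null(instance) || nrow(instance) == 0L) stop("empty skeleton instance")
  if (nrow(instance) == 1L) return(0)
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  g <- skeleton_graph(instance, spacing)
  deg <- igraph::degree(g)
  ends <- which(deg <= 1L)
  if (length(ends) < 2L) ends <- seq_len(nrow(instance)) # cycle: fall back to all pairs
  dm <- igraph::distances(g, v = ends, to = ends, weights = igraph::E(g)$weight)
  dm[!is.finite(dm)] <- 0
  best <- arrayInd(which.max(dm), dim(dm))
  vp <- as.integer(igraph::shortest_paths(g, from = ends[best[1]], to = ends[best[2]],
                                          weights = igraph::E(g)$weight)$vpath[[1]])
  path <- sweep(instance[vp, , drop = FALSE] - 0.5, 2L, spacing, "*")
  r_med <- if (!is.null(radius)) stats::median(radius[vp]) else NA_real_
  if (!is.null(mask) && is.finite(r_med))
    path <- recentre_path(path, mask, spacing[1], r_med)
  path <- smooth_path(path, smooth_window)
  if (nrow(path) < 2L) return(max(dm))
  len <- sum(sqrt(rowSums(diff(path)^2)))
  if (!is.null(mask) && is.finite(r_med)) {
    # measure the cap overshoot per end: walk outward along the end tangent
    # to the mask boundary (distance w); the central axis truly ends one
    # tube radius r before that boundary, so the signed correction is w - r
    n <- nrow(path)
    k <- min(4L, n - 1L)
    t1 <- path[1L, ] - path[1L + k, ]; t1 <- t1 / sqrt(sum(t1^2))
    t2 <- path[n, ] - path[n - k, ]; t2 <- t2 / sqrt(sum(t2^2))
    w1 <- walk_to_boundary(path[1L, ], t1, mask, spacing[1])
    w2 <- walk_to_boundary(path[n, ], t2, mask, spacing[1])
    len <- max(len + (w1 - r_med) + (w2 - r_med), 0)
  } else if (is.finite(r_med)) {
    # without the mask, assume the tip voxel centre sits about half a voxel
    # inside the cap surface
    len <- max(len - 2 * max(r_med - spacing[1] / 2, 0), 0)
  }
  len
}

# distance from a point to the mask boundary along a fixed direction
walk_to_boundary <- function(p, t, mask, sp, step = 0.05, max_walk = 2) {
  d <- dim(mask)
  s <- 0
  repeat {
    s <- s + step
    v <- pmin(pmax(round((p + s * t) / sp + 0.5), 1), d)
    if (!mask[v[1], v[2], v[3]] || s > max_walk) return(s)
  }
}

# move each point to the centroid of the mask voxels in a thin slab
# perpendicular to its local tangent (sub-voxel re-centring); only the
# perpendicular component is applied so axial positions are untouched
recentre_points <- function(pts0, tangents, mask, sp, rad) {
  d <- dim(mask)
  rho <- rad + 0.5 * sp
  out <- pts0
  for (i in seq_len(nrow(pts0))) {
    tg <- tangents[i, ]
    nt <- sqrt(sum(tg^2)); if (nt == 0 || !is.finite(nt)) next
    tg <- tg / nt
    p <- out[i, ]
    lo <- pmax(floor(p / sp - rho / sp + 0.5), 1)
    hi <- pmin(ceiling(p / sp + rho / sp + 0.5), d)
    zi <- lo[1]:hi[1]; yi <- lo[2]:hi[2]; xi <- lo[3]:hi[3]
    sub <- mask[zi, yi, xi, drop = FALSE]
    if (!any(sub)) next
    w <- which(sub, arr.ind = TRUE)
    pts <- cbind((zi[w[, 1]] - 0.5) * sp, (yi[w[, 2]] - 0.5) * sp,
                 (xi[w[, 3]] - 0.5) * sp)
    rel <- sweep(pts, 2L, p)
    ax <- rel %*% tg
    perp2 <- rowSums(rel^2) - ax^2
    keep <- abs(ax) <= 0.6 * sp & perp2 <= rho^2
    if (!any(keep)) next
    cen <- colMeans(pts[keep, , drop = FALSE])
    dv <- cen - p
    dv <- dv - sum(dv * tg) * tg
    out[i, ] <- p + dv
  }
  out
}

recentre_path <- function(path, mask, sp, rad, iters = 2L) {
  n <- nrow(path)
  for (it in seq_len(iters)) {
    j0 <- pmax(seq_len(n) - 2L, 1L); j1 <- pmin(seq_len(n) + 2L, n)
    path <- recentre_points(path, path[j1, , drop = FALSE] - path[j0, , drop = FALSE],
                            mask, sp, rad)
  }
  path
}

# sub-voxel central-axis point set of an instance for distance refinement:
# every voxel re-centred on its cross-section centroid, graph-neighbour
# smoothed, with the cap/tip neighbourhoods dropped (anchored tips sit on
# the blur-elongated mask surface, off the true axis)
refined_axis_points <- function(skels, i) {
  inst <- skels$instances[[i]]
  co <- recentre_instance(skels, i)
  if (nrow(inst) < 4L) return(co)
  g <- skeleton_graph(inst, skels$spacing)
  deg <- igraph::degree(g)
  adj <- igraph::as_adj_list(g)
  sm <- co
  for (v in seq_len(nrow(co))) {
    nbs <- as.integer(adj[[v]])
    if (length(nbs) == 2L) sm[v, ] <- (co[v, ] + co[nbs[1], ] + co[nbs[2], ]) / 3
  }
  co <- sm
  tips <- which(deg <= 1L)
  if (length(tips) == 0L) return(co)
  r <- stats::median(skels$radius[[i]])
  k <- ceiling(r / skels$spacing[1])
  hop <- suppressWarnings(igraph::distances(g, v = tips, weights = NA))
  near_tip <- apply(hop, 2L, min) <= k
  if (sum(!near_tip) >= 3L) co[!near_tip, , drop = FALSE] else co
}

# re-centre every skeleton voxel of an instance (tangents from graph
# neighbours); junction voxels (degree > 2) are left at their voxel centre
recentre_instance <- function(skels, i, iters = 2L) {
  inst <- skels$instances[[i]]
  co <- skels$coords[[i]]
  if (nrow(inst) < 2L || is.null(skels$mask)) return(co)
  g <- skeleton_graph(inst, skels$spacing)
  deg <- igraph::degree(g)
  adj <- igraph::as_adj_list(g)
  tg <- matrix(0, nrow(inst), 3L)
  for (v in seq_len(nrow(inst))) {
    nbs <- as.integer(adj[[v]])
    if (deg[v] == 2L) tg[v, ] <- co[nbs[2], ] - co[nbs[1], ]
    else if (deg[v] == 1L) tg[v, ] <- co[v, ] - co[nbs[1], ]
    # junctions: zero tangent -> recentre_points skips them
  }
  r <- stats::median(skels$radius[[i]])
  for (it in seq_len(iters))
    co <- recentre_points(co, tg, skels$mask, skels$spacing[1], r)
  co
}

# symmetric truncated moving average: window shrinks near the ends so the
# path endpoints stay fixed (an asymmetric window would drag them inward
# and shorten the measured curve)
smooth_path <- function(p, w) {
  n <- nrow(p)
  if (w <= 1L || n < 3L) return(p)
  h <- w %/% 2L
  out <- p
  for (i in seq_len(n)) {
    hh <- min(h, i - 1L, n - i)
    if (hh < 1L) next
    j <- (i - hh):(i + hh)
    out[i, ] <- colMeans(p[j, , drop = FALSE])
  }
  out
}

#' Refined (sub-voxel) central-axis paths of a skeleton set
#'
#' For each instance, extracts the longest geodesic path, re-centres each
#' vertex on the tube cross-section centroid of the source mask and applies
#' light smoothing — the sub-voxel central axis used for refined
#' skeleton-to-skeleton distances.
#'
#' @param skels a [skeleton_set()].
#' @param densify insert midpoints this many times (halving vertex spacing
#'   per round) to reduce vertex-sampling error.
#' @return list of coordinate matrices (um; columns z, y, x).
#' @export
skeleton_paths <- function(skels, densify = 1L) {
  stopifnot(inherits(skels, "skeleton_set"))
  lapply(seq_along(skels$instances), function(i) {
    inst <- skels$instances[[i]]
    if (nrow(inst) < 2L) return(skels$coords[[i]])
    g <- skeleton_graph(inst, skels$spacing)
    deg <- igraph::degree(g)
    ends <- which(deg <= 1L)
    if (length(ends) < 2L) ends <- seq_len(nrow(inst))
    dm <- igraph::distances(g, v = ends, to = ends, weights = igraph::E(g)$weight)
    dm[!is.finite(dm)] <- 0
    b <- arrayInd(which.max(dm), dim(dm))
    vp <- as.integer(igraph::shortest_paths(g, from = ends[b[1]], to = ends[b[2]],
                                            weights = igraph::E(g)$weight)$vpath[[1]])
    path <- sweep(inst[vp, , drop = FALSE] - 0.5, 2L, skels$spacing, "*")
    r <- stats::median(skels$radius[[i]][vp])
    if (!is.null(skels$mask))
      path <- recentre_path(path, skels$mask, skels$spacing[1], r)
    path <- smooth_path(path, 3L)
    for (k in seq_len(densify)) {
      n <- nrow(path)
      if (n < 2L) break
      mid <- (path[-n, , drop = FALSE] + path[-1, , drop = FALSE]) / 2
      out <- matrix(0, 2L * n - 1L, 3L)
      out[seq(1L, 2L * n - 1L, 2L), ] <- path
      out[seq(2L, 2L * n - 2L, 2L), ] <- mid
      path <- out
    }
    path
  })
}
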