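#' Parameters for synthetic axo-ciliary scenes
#'
#' Defines the study conditions the generator emulates: a dense band of
#' pyramidal-layer nuclei, tubular cilia emanating from nucleus surfaces
#' (lognormal length, median ~7 um), tortuous axons with 1-3 um-spaced
#' varicosities, planted cilium-axon minimum distances, diffraction-limited
#' puncta, receptor enrichment on ciliary subsegments, Gaussian PSF blur
#' and Poisson + Gaussian read noise.
#'
#' Each cilium is a planar constant-z arc; its paired axon is the same arc
#' translated by a pure z offset and extended along its end tangents, so
#' the true minimum centre-axis distance equals the planted offset exactly.
#' Placement is verified against all other axons and retried (bounded) so
#' the planted distance is always the global minimum.
#'
#' @param n_cilia number of in-layer cilia (one paired axon each).
#' @param planted_distances um; recycled to `n_cilia`. Defaults alternate
#'   contacting (0.5-1.5 um) and non-contacting (2.5-3.5 um) values, all
#'   at least 0.5 um from the 2-um cutoff.
#' @param spacing_um isotropic voxel size.
#' @param cell_pitch_um placement-cell size along x/y.
#' @param length_median_um,length_sdlog lognormal cilium arc length.
#' @param tube_radius_um,axon_radius_um tube radii.
#' @param nucleus_radius_um nucleus sphere radius.
#' @param n_scatter_nuclei nuclei (with cilia) outside the layer band.
#' @param boundary_cilium add one cilium touching the volume face.
#' @param n_puncta_assoc,n_puncta_far puncta planted on / far from axons.
#' @param varicosity_pitch_um,varicosity_radius_um varicosity geometry.
#' @param receptor_in_fraction planted fraction of supra-threshold receptor
#'   signal inside cilia.
#' @param psf_sigma_um PSF sigma (z, y, x) in um.
#' @param photon_scale peak signal in photons for the noise model.
#' @param read_noise_sd Gaussian read noise SD (photons).
#' @param noise,blur apply the noise / PSF stages.
#' @param seed integer seed; identical params + seed give bit-identical
#'   scenes.
#' @return list of class `scene_params`.
#' @export
scene_params <- function(n_cilia = 20L,
                         planted_distances = NULL,
                         spacing_um = 0.2,
                         cell_pitch_um = 12,
                         length_median_um = 7.0,
                         length_sdlog = 0.25,
                         tube_radius_um = 0.3,
                         axon_radius_um = 0.3,
                         nucleus_radius_um = 1.8,
                         n_scatter_nuclei = 3L,
                         boundary_cilium = TRUE,
                         n_puncta_assoc = 15L,
                         n_puncta_far = 15L,
                         varicosity_pitch_um = 2.0,
                         varicosity_radius_um = 0.45,
                         receptor_in_fraction = 0.6,
                         psf_sigma_um = c(0.3, 0.1, 0.1),
                         photon_scale = 200,
                         read_noise_sd = 2,
                         noise = TRUE,
                         blur = TRUE,
                         seed = 1L) {
  if (is.null(planted_distances)) {
    contacting <- seq(0.5, 1.5, length.out = ceiling(n_cilia / 2))
    apart <- seq(2.5, 3.5, length.out = floor(n_cilia / 2))
    planted_distances <- as.vector(rbind(contacting[seq_len(ceiling(n_cilia / 2))],
                                         c(apart, NA)[seq_len(ceiling(n_cilia / 2))]))
    planted_distances <- planted_distances[!is.na(planted_distances)][seq_len(n_cilia)]
  }
  planted_distances <- rep_len(planted_distances, n_cilia)
  stopifnot(all(planted_distances > 0), spacing_um > 0, length_median_um > 0)
  structure(as.list(environment()), class = "scene_params")
}

# deterministic substream: each structure stage reseeds from the scene seed
sub_seed <- function(seed, k) (as.integer(seed) * 1009L + k * 7919L) %% 2147483000L

# sample an arc (constant-z planar curve) of arc length L inside a cell
# centred at (cy, cx); returns matrix of um coords (z, y, x), step ds
make_arc <- function(L, z, cy, cx, ds = 0.1, base_near_row = FALSE) {
  turn <- stats::runif(1, 3.8, 4.5)           # total heading change, rad
  R <- L / turn
  # base_near_row pins the arc base close to the row line (phi ~ 0 or pi)
  # so the owning nucleus stays within ~2 um of the row in y
  phi0 <- if (base_near_row) sample(c(0, pi), 1) + stats::runif(1, -0.3, 0.3)
          else stats::runif(1, 0, 2 * pi)
  s <- seq(0, L, by = ds)
  if (s[length(s)] < L) s <- c(s, L)
  dirsign <- sample(c(-1, 1), 1)
  phi <- phi0 + dirsign * s / R
  # arc on a circle of radius R around a jittered centre
  ccy <- cy + stats::runif(1, -0.4, 0.4)
  ccx <- cx + stats::runif(1, -0.4, 0.4)
  cbind(z = rep(z, length(s)),
        y = ccy + R * sin(phi),
        x = ccx + R * cos(phi))
}

# extend a polyline beyond both ends along its end tangents
extend_polyline <- function(p, by_um, ds = 0.1) {
  n <- nrow(p)
  t1 <- p[1, ] - p[2, ]; t1 <- t1 / sqrt(sum(t1^2))
  t2 <- p[n, ] - p[n - 1, ]; t2 <- t2 / sqrt(sum(t2^2))
  s <- seq(ds, by_um, by = ds)
  pre <- sweep(outer(rev(s), t1), 2, p[1, ], "+")
  post <- sweep(outer(s, t2), 2, p[n, ], "+")
  rbind(pre, p, post)
}

# minimum distance between two polylines (vertex-to-vertex)
polyline_dist <- function(a, b) {
  dd <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * a %*% t(b)
  sqrt(max(min(dd), 0))
}

# stamp a tube of radius r (um) around polyline points into arr (additive max)
raster_tube <- function(arr, spacing, pts, radius, value = 1) {
  d <- dim(arr)
  rv <- ceiling(radius / spacing)
  for (i in seq_len(nrow(pts))) {
    v <- pts[i, ] / spacing + 0.5            # fractional voxel index
    lo <- pmax(floor(v - rv), 1)
    hi <- pmin(ceiling(v + rv), d)
    if (any(lo > hi)) next
    zi <- lo[1]:hi[1]; yi <- lo[2]:hi[2]; xi <- lo[3]:hi[3]
    dz <- (zi - 0.5) * spacing[1] - pts[i, 1]
    dy <- (yi - 0.5) * spacing[2] - pts[i, 2]
    dx <- (xi - 0.5) * spacing[3] - pts[i, 3]
    box <- outer(outer(dz^2, dy^2, "+"), dx^2, "+") <= radius^2
    sub <- arr[zi, yi, xi, drop = FALSE]
    sub[box] <- pmax(sub[box], value)
    arr[zi, yi, xi] <- sub
  }
  arr
}

# stamp a solid sphere
raster_sphere <- function(arr, spacing, center, radius, value = 1) {
  raster_tube(arr, spacing, matrix(center, 1), radius, value)
}

apply_noise <- function(arr, params) {
  if (params$blur) {
    sv <- params$psf_sigma_um / rep_len(params$spacing_um, 3L)
    arr <- gauss3(arr, sv)
  }
  if (params$noise) {
    lam <- arr * params$photon_scale
    arr <- stats::rpois(length(lam), lam) +
      stats::rnorm(length(lam), 0, params$read_noise_sd)
    arr <- array(pmax(arr, 0), dim(lam))
  } else {
    arr <- arr * params$photon_scale
  }
  arr
}

#' Generate a synthetic contact scene with known ground truth
#'
#' Builds the five stained channels of the contact-mapping pipeline —
#' nuclei (Hoechst-like), cilia (ADCY3-like), axons (SERT-like), puncta
#' (synaptophysin-like) and receptor (5-HTR6-like, enriched on ciliary
#' subsegments) — together with a self-consistent truth table (per-cilium
#' arc length, exact planted minimum axon distance, contact label, owning
#' nucleus and layer membership; puncta coordinates and association
#' labels; the planted ciliary receptor fraction).
#'
#' @param params a [scene_params()].
#' @param channels subset of channels to rasterize (default all).
#' @return list: `volume` (a [multichannel_volume()]), `truth` (list).
#' @export
make_contact_scene <- function(params = scene_params(),
                               channels = c("nuclei", "cilia", "axons",
                                            "puncta", "receptor")) {
  stopifnot(inherits(params, "scene_params"))
  p <- params
  sp <- rep_len(p$spacing_um, 3L)
  ncol_cells <- ceiling(p$n_cilia / 2)
  pitch <- p$cell_pitch_um
  ext <- c(z = 9.6, y = 2 * pitch + 16, x = ncol_cells * pitch)
  d <- as.integer(round(ext / sp))
  band_y <- c(ext[["y"]] / 2 - pitch / 2, ext[["y"]] / 2 + pitch / 2) # two row centres

  # --- plan cilium/axon geometry with bounded retries -------------------
  set.seed(sub_seed(p$seed, 1L))
  lengths <- stats::rlnorm(p$n_cilia, log(p$length_median_um), p$length_sdlog)
  lengths <- pmin(pmax(lengths, 3), 12)
  paths <- vector("list", p$n_cilia)
  axons <- vector("list", p$n_cilia)
  nuc_centers <- matrix(0, 0, 3)
  nuc_in_band <- logical(0)
  cil_nucleus <- integer(p$n_cilia)
  for (i in seq_len(p$n_cilia)) {
    row <- ((i - 1L) %% 2L) + 1L
    col <- ((i - 1L) %/% 2L) + 1L
    cy <- band_y[row]
    cx <- (col - 0.5) * pitch
    zc <- ext[["z"]] / 2 + stats::runif(1, -0.4, 0.4)
    ok <- FALSE
    for (try in 1:40) {
      arc <- make_arc(lengths[i], zc, cy, cx, base_near_row = TRUE)
      dzi <- p$planted_distances[i] * sample(c(-1, 1), 1)
      if (zc + dzi < 1.2 || zc + dzi > ext[["z"]] - 1.2) dzi <- -dzi
      if (zc + dzi < 1.2 || zc + dzi > ext[["z"]] - 1.2) next
      ax <- extend_polyline(arc, 3.0)
      ax[, 1] <- ax[, 1] + dzi
      inside <- function(m, margin)
        all(m[, 1] > margin & m[, 1] < ext[["z"]] - margin &
              m[, 2] > margin & m[, 2] < ext[["y"]] - margin &
              m[, 3] > margin & m[, 3] < ext[["x"]] - margin)
      if (!inside(arc, 0.8) || !inside(ax, 0.8)) next
      # planted distance must be the global minimum over all axons
      clash <- FALSE
      for (j in seq_len(i - 1L)) {
        if (polyline_dist(arc, axons[[j]]) < p$planted_distances[i] + 0.5 ||
            polyline_dist(paths[[j]], ax) < p$planted_distances[j] + 0.5) {
          clash <- TRUE; break
        }
      }
      if (clash) next
      paths[[i]] <- arc; axons[[i]] <- ax; ok <- TRUE; break
    }
    if (!ok) stop(sprintf("could not place cilium %d without violating planted distances", i))
    # owning nucleus: sphere touching the cilium base, pushed away along the base tangent
    base_dir <- paths[[i]][1, ] - paths[[i]][2, ]
    base_dir <- base_dir / sqrt(sum(base_dir^2))
    ncen <- paths[[i]][1, ] - base_dir * p$nucleus_radius_um
    ncen <- pmin(pmax(ncen, p$nucleus_radius_um * 0.6),
                 ext - p$nucleus_radius_um * 0.6)
    nuc_centers <- rbind(nuc_centers, ncen)
    nuc_in_band <- c(nuc_in_band, TRUE)
    cil_nucleus[i] <- nrow(nuc_centers)
  }

  # filler nuclei make the pyramidal band dense and contiguous: candidate
  # positions every 2.5 um along both row lines and the mid line between
  # them, kept only when at least one nucleus diameter from every other
  # nucleus (so touching nuclei never occur and centre counting stays
  # exact); modest dilation then merges the band into one component while
  # scattered nuclei stay separate
  set.seed(sub_seed(p$seed, 7L))
  min_sep <- 2 * p$nucleus_radius_um + 0.1
  for (ry in c(band_y, ext[["y"]] / 2)) {
    for (mx in seq(1.5, ext[["x"]] - 1.5, by = 2.5)) {
      cand <- c(ext[["z"]] / 2 + stats::runif(1, -0.5, 0.5),
                ry + stats::runif(1, -0.4, 0.4),
                mx + stats::runif(1, -0.3, 0.3))
      dmin <- sqrt(min(colSums((t(nuc_centers) - cand)^2)))
      if (dmin >= min_sep) {
        nuc_centers <- rbind(nuc_centers, cand)
        nuc_in_band <- c(nuc_in_band, TRUE)
      }
    }
  }

  # scattered out-of-band nuclei, each with an (excluded) cilium
  set.seed(sub_seed(p$seed, 2L))
  scatter_paths <- list()
  for (k in seq_len(p$n_scatter_nuclei)) {
    sy <- if (k %% 2L == 0L) 2.4 else ext[["y"]] - 2.4
    sx <- stats::runif(1, 4, ext[["x"]] - 4)
    sz <- ext[["z"]] / 2 + stats::runif(1, -1, 1)
    nuc_centers <- rbind(nuc_centers, c(sz, sy, sx))
    nuc_in_band <- c(nuc_in_band, FALSE)
    arc <- make_arc(5, sz, sy, sx)
    scatter_paths[[k]] <- arc
  }
  boundary_path <- NULL
  if (isTRUE(p$boundary_cilium)) {
    # straight cilium running into the x = 0 face
    zc <- ext[["z"]] / 2
    yc <- ext[["y"]] / 2
    s <- seq(0, 4, by = 0.1)
    boundary_path <- cbind(z = rep(zc, length(s)), y = rep(yc, length(s)), x = s)
  }

  # --- rasterize --------------------------------------------------------
  empty <- function() array(0, d)
  out <- list()
  truth_masks <- list()
  if ("nuclei" %in% channels) {
    a <- empty()
    for (i in seq_len(nrow(nuc_centers)))
      a <- raster_sphere(a, sp, nuc_centers[i, ], p$nucleus_radius_um)
    truth_masks$nuclei <- a > 0
    out$nuclei <- a
  }
  all_cilia <- c(paths, scatter_paths, if (!is.null(boundary_path)) list(boundary_path))
  if ("cilia" %in% channels) {
    a <- empty()
    for (pp in all_cilia) a <- raster_tube(a, sp, pp, p$tube_radius_um)
    truth_masks$cilia <- a > 0
    out$cilia <- a
  }
  if ("axons" %in% channels) {
    a <- empty()
    for (ax in axons) a <- raster_tube(a, sp, ax, p$axon_radius_um)
    # varicosities: brighter swellings along each axon
    set.seed(sub_seed(p$seed, 3L))
    vari <- list()
    for (ax in axons) {
      steps <- cumsum(c(0, sqrt(rowSums(diff(ax)^2))))
      at <- seq(p$varicosity_pitch_um / 2, max(steps), by = p$varicosity_pitch_um)
      vi <- vapply(at, function(s) which.min(abs(steps - s)), integer(1))
      for (v in vi) a <- raster_sphere(a, sp, ax[v, ], p$varicosity_radius_um, value = 2)
      vari[[length(vari) + 1L]] <- ax[vi, , drop = FALSE]
    }
    truth_masks$axons <- a > 0
    out$axons <- a
    varicosity_pts <- do.call(rbind, vari)
  } else varicosity_pts <- NULL

  puncta_truth <- NULL
  if ("puncta" %in% channels) {
    set.seed(sub_seed(p$seed, 4L))
    a <- empty()
    pts <- matrix(0, 0, 3); assoc <- logical(0)
    if (!is.null(varicosity_pts) && nrow(varicosity_pts) > 0) {
      vi <- sample.int(nrow(varicosity_pts), min(p$n_puncta_assoc, nrow(varicosity_pts)))
      for (v in vi) {
        pos <- varicosity_pts[v, ] + stats::runif(3, -0.2, 0.2)
        pts <- rbind(pts, pos); assoc <- c(assoc, TRUE)
      }
    }
    tries <- 0L
    while (sum(!assoc) < p$n_puncta_far && tries < 2000L) {
      tries <- tries + 1L
      pos <- c(stats::runif(1, 1, ext[["z"]] - 1),
               stats::runif(1, 1, ext[["y"]] - 1),
               stats::runif(1, 1, ext[["x"]] - 1))
      dmin <- min(vapply(axons, function(ax) polyline_dist(matrix(pos, 1), ax), numeric(1)))
      if (dmin >= 1.5) { pts <- rbind(pts, pos); assoc <- c(assoc, FALSE) }
    }
    for (i in seq_len(nrow(pts))) a <- raster_sphere(a, sp, pts[i, ], 0.25)
    out$puncta <- a
    puncta_truth <- data.frame(z = pts[, 1], y = pts[, 2], x = pts[, 3],
                               associated = assoc)
  }

  receptor_truth <- NULL
  if ("receptor" %in% channels) {
    set.seed(sub_seed(p$seed, 5L))
    a_in <- empty()
    for (pp in paths) a_in <- raster_tube(a_in, sp, pp, p$tube_radius_um)
    # extra-ciliary receptor blobs sized to the planted in/out split
    a_out <- empty()
    n_blobs <- 8L
    for (k in seq_len(n_blobs)) {
      for (try in 1:200) {
        pos <- c(stats::runif(1, 1.5, ext[["z"]] - 1.5),
                 stats::runif(1, 1.5, ext[["y"]] - 1.5),
                 stats::runif(1, 1.5, ext[["x"]] - 1.5))
        dmin <- min(vapply(paths, function(pp) polyline_dist(matrix(pos, 1), pp), numeric(1)))
        if (dmin >= 2.5) break
      }
      a_out <- raster_sphere(a_out, sp, pos, 0.5)
    }
    s_in <- sum(a_in); s_out <- sum(a_out)
    # scale the outside blobs so in/(in+out) hits the planted fraction
    w <- s_in * (1 - p$receptor_in_fraction) / (p$receptor_in_fraction * s_out)
    a <- a_in + w * a_out
    receptor_truth <- list(in_fraction = s_in / (s_in + w * s_out),
                           outside_weight = w)
    out$receptor <- a
  }

  set.seed(sub_seed(p$seed, 6L))
  vols <- lapply(names(out), function(nm)
    voxel_volume(apply_noise(out[[nm]], p), sp, channel = nm))
  names(vols) <- names(out)

  truth <- list(
    params = p,
    dim = d, extent_um = ext, spacing = sp,
    cilia = data.frame(id = seq_len(p$n_cilia),
                       length_um = lengths,
                       planted_distance_um = p$planted_distances,
                       contact = p$planted_distances <= 2.0,
                       nucleus = cil_nucleus,
                       in_layer = TRUE),
    cilium_paths = paths,
    axon_paths = axons,
    scatter_paths = scatter_paths,
    boundary_path = boundary_path,
    nucleus_centers = nuc_centers,
    nucleus_in_band = nuc_in_band,
    puncta = puncta_truth,
    receptor = receptor_truth,
    masks = truth_masks
  )
  list(volume = multichannel_volume(vols), truth = truth)
}

#' Generate a synthetic ratiometric (marker/DNA) scene
#'
#' Nuclei with per-nucleus planted marker-to-DNA ratios; a known
#' multiplicative exponential z attenuation is applied to the marker
#' channel (the DNA channel is left unattenuated, mimicking
#' antibody-penetration depth loss).
#'
#' @param n_nuclei nuclei count.
#' @param ratios per-nucleus ratios (recycled), or `NULL` to draw from a
#'   lognormal with `ratio_meanlog`, `ratio_sdlog`.
#' @param ratio_meanlog,ratio_sdlog lognormal parameters of planted ratios.
#' @param attenuation_z0_um e-folding depth of the planted marker
#'   attenuation (`Inf` disables it).
#' @param spacing_um isotropic voxel size (default 0.15).
#' @param dim_zyx volume dimensions.
#' @param dna_level DNA-channel intensity inside nuclei.
#' @param noise_sd additive Gaussian noise SD (0 disables).
#' @param seed RNG seed.
#' @return list: `volume` (channels `marker`, `dna`), `truth` (ratios,
#'   attenuation vector, nucleus centres/labels).
#' @export
make_ratiometric_scene <- function(n_nuclei = 12L, ratios = NULL,
                                   ratio_meanlog = log(1.1), ratio_sdlog = 0.15,
                                   attenuation_z0_um = Inf,
                                   spacing_um = 0.15,
                                   dim_zyx = c(40L, 96L, 96L),
                                   dna_level = 100,
                                   noise_sd = 0,
                                   seed = 1L) {
  sp <- rep_len(spacing_um, 3L)
  d <- as.integer(dim_zyx)
  ext <- d * sp
  set.seed(sub_seed(seed, 11L))
  if (is.null(ratios)) ratios <- stats::rlnorm(n_nuclei, ratio_meanlog, ratio_sdlog)
  ratios <- rep_len(ratios, n_nuclei)
  r_nuc <- 1.6
  centers <- matrix(0, n_nuclei, 3)
  ngrid <- ceiling(sqrt(n_nuclei))
  for (i in seq_len(n_nuclei)) {
    gy <- ((i - 1L) %% ngrid) + 1L
    gx <- ((i - 1L) %/% ngrid) + 1L
    centers[i, ] <- c(ext[1] / 2 + stats::runif(1, -ext[1] / 6, ext[1] / 6),
                      (gy - 0.5) * ext[2] / ngrid,
                      (gx - 0.5) * ext[3] / ngrid)
  }
  dna <- array(0, d); lab <- array(0L, d)
  for (i in seq_len(n_nuclei)) {
    m <- array(0, d)
    m <- raster_sphere(m, sp, centers[i, ], r_nuc)
    dna <- dna + m
    lab[m > 0] <- i
  }
  dna <- pmin(dna, 1) * dna_level
  marker <- dna
  for (i in seq_len(n_nuclei)) marker[lab == i] <- dna[lab == i] * ratios[i]
  zvec <- if (is.finite(attenuation_z0_um))
    exp(-((seq_len(d[1]) - 0.5) * sp[1]) / attenuation_z0_um) else rep(1, d[1])
  marker <- marker * array(zvec, d)
  # dense reference stain: diffuse antibody-like signal that fills the slab
  # (content homogeneous in z at the projection scale), carrying the same
  # depth attenuation; this is the channel flat-field estimation relies on
  tex <- gauss3(array(stats::runif(prod(d)), d), 3)
  reference <- (dna_level * (0.9 + 0.2 * (tex - mean(tex)) / max(abs(tex - mean(tex))))) *
    array(zvec, d)
  if (noise_sd > 0) {
    dna <- dna + array(stats::rnorm(length(dna), 0, noise_sd), d)
    marker <- marker + array(stats::rnorm(length(marker), 0, noise_sd), d)
    reference <- reference + array(stats::rnorm(length(reference), 0, noise_sd), d)
    dna <- pmax(dna, 0); marker <- pmax(marker, 0); reference <- pmax(reference, 0)
  }
  vol <- multichannel_volume(list(
    marker = voxel_volume(marker, sp, channel = "marker"),
    dna = voxel_volume(dna, sp, channel = "dna"),
    reference = voxel_volume(reference, sp, channel = "reference")))
  list(volume = vol,
       truth = list(ratios = ratios, centers = centers, labels = lab,
                    attenuation = zvec, attenuation_z0_um = attenuation_z0_um,
                    spacing = sp, seed = seed))
}

#' Generate a synthetic FLIM scene
#'
#' A ciliary tube whose voxels carry photon counts and lifetimes: counts
#' are Poisson around `high_counts` with a stated fraction of voxels drawn
#' around `low_counts` (below the 50-count filter); lifetimes are drawn
#' from a three-parameter alpha distribution (or a two-population
#' quenched/unquenched mixture). Optionally, sub-filter voxels are
#' assigned adversarial lifetimes to exercise the filter contract.
#'
#' @param shape,location,scale alpha-distribution parameters of the
#'   lifetime field (ns).
#' @param lifetimes `"alpha"` or `"mixture"` (1.3 / 2.7 ns populations).
#' @param mixture_fraction quenched fraction under `"mixture"`.
#' @param low_fraction fraction of ciliary voxels with low counts.
#' @param high_counts,low_counts Poisson means.
#' @param adversarial_low assign 10 ns lifetimes to sub-filter voxels.
#' @param dim_zyx,spacing_um grid geometry.
#' @param seed RNG seed.
#' @return list: `flim` (a [flim_volume()]), `mask` (ciliary
#'   [binary_mask()]), `truth` (parameters and the closed-form mode).
#' @export
make_flim_scene <- function(shape = 3, location = 1.2, scale = 1.5,
                            lifetimes = c("alpha", "mixture"),
                            mixture_fraction = 0.5,
                            low_fraction = 0.2,
                            high_counts = 300, low_counts = 25,
                            adversarial_low = FALSE,
                            dim_zyx = c(24L, 48L, 48L), spacing_um = 0.3,
                            seed = 1L) {
  lifetimes <- match.arg(lifetimes)
  sp <- rep_len(spacing_um, 3L)
  d <- as.integer(dim_zyx)
  ext <- d * sp
  set.seed(sub_seed(seed, 21L))
  s <- seq(1.5, ext[3] - 1.5, by = 0.15)
  path <- cbind(z = ext[1] / 2 + 1.5 * sin(s / 3),
                y = ext[2] / 2 + 2.5 * cos(s / 4), x = s)
  m <- array(0, d)
  m <- raster_tube(m, sp, path, 0.45)
  mask <- m > 0
  nvox <- sum(mask)
  low <- stats::runif(nvox) < low_fraction
  counts <- integer(nvox)
  counts[!low] <- stats::rpois(sum(!low), high_counts)
  counts[low] <- pmin(stats::rpois(sum(low), low_counts), 49L)
  lt <- if (lifetimes == "alpha") ralpha(nvox, shape, location, scale)
        else ifelse(stats::runif(nvox) < mixture_fraction, 1.3, 2.7)
  if (adversarial_low) lt[low] <- 10
  carr <- array(0L, d); aarr <- array(0, d)
  carr[mask] <- counts
  aarr[mask] <- lt
  # dim autofluorescent background outside the cilium
  bgsel <- !mask & stats::runif(length(m)) < 0.05
  carr[bgsel] <- stats::rpois(sum(bgsel), 5)
  aarr[bgsel] <- pmax(stats::rnorm(sum(bgsel), 0.3, 0.05), 0.01)
  truth_mode <- if (lifetimes == "alpha") alpha_mode(shape, location, scale) else NA_real_
  list(flim = flim_volume(carr, aarr, sp),
       mask = binary_mask(mask, sp),
       truth = list(shape = shape, location = location, scale = scale,
                    lifetimes = lifetimes, mode = truth_mode,
                    low_voxels = low, seed = seed))
}

#' Generate synthetic sensor traces and dose-response sets
#'
#' Stimulus-locked dF/F traces with exponential on/off kinetics and known
#' amplitude, plus Hill-equation titration sets at the sensor EC50 scales
#' (84 nM for the plasma-membrane sensor, 28 nM for the cilia-targeted
#' sensor).
#'
#' @param rate_hz sampling rate.
#' @param n_baseline baseline frames before stimulation.
#' @param stim_s stimulus duration in s.
#' @param post_s post-stimulus duration in s.
#' @param amplitude peak dF/F of the response.
#' @param tau_on_s,tau_off_s kinetic time constants.
#' @param f_base baseline fluorescence; `background` additive offset.
#' @param noise_sd Gaussian noise SD on F (0 = noiseless).
#' @param ec50_m EC50s (molar) of the generated titration sets.
#' @param hill Hill slope; `top` saturating dF/F per set (recycled).
#' @param n_doses doses per titration set (log-spaced around EC50).
#' @param seed RNG seed.
#' @return list: `trace` (a [sensor_trace()]), `stim_window`, `baseline_window`,
#'   `dose_sets` (list of data.frames conc/resp), `truth`.
#' @export
make_traces <- function(rate_hz = 5, n_baseline = 10L, stim_s = 10, post_s = 30,
                        amplitude = 0.15, tau_on_s = 0.19, tau_off_s = 8.46,
                        f_base = 100, background = 10, noise_sd = 0,
                        ec50_m = c(84e-9, 28e-9), hill = 1,
                        top = c(0.30, 0.40), n_doses = 8L, seed = 1L) {
  set.seed(sub_seed(seed, 31L))
  dt <- 1 / rate_hz
  n_stim <- round(stim_s * rate_hz); n_post <- round(post_s * rate_hz)
  n <- n_baseline + n_stim + n_post
  t <- (seq_len(n) - 1) * dt
  g <- numeric(n)
  t_on <- t[(n_baseline + 1):(n_baseline + n_stim)] - t[n_baseline + 1]
  g[(n_baseline + 1):(n_baseline + n_stim)] <- 1 - exp(-t_on / tau_on_s)
  g_end <- g[n_baseline + n_stim]
  t_off <- t[(n_baseline + n_stim + 1):n] - t[n_baseline + n_stim]
  g[(n_baseline + n_stim + 1):n] <- g_end * exp(-t_off / tau_off_s)
  F <- background + f_base * (1 + amplitude * g)
  if (noise_sd > 0) F <- F + stats::rnorm(n, 0, noise_sd)
  tr <- sensor_trace(t, F)
  top <- rep_len(top, length(ec50_m))
  dose_sets <- lapply(seq_along(ec50_m), function(k) {
    conc <- 10^seq(log10(ec50_m[k]) - 2, log10(ec50_m[k]) + 2, length.out = n_doses)
    resp <- top[k] / (1 + (ec50_m[k] / conc)^hill)
    if (noise_sd > 0) resp <- resp * (1 + stats::rnorm(n_doses, 0, noise_sd / f_base))
    data.frame(conc = conc, resp = resp)
  })
  names(dose_sets) <- paste0("ec50_", signif(ec50_m * 1e9, 3), "nM")
  list(trace = tr,
       baseline_window = seq_len(n_baseline),
       stim_window = (n_baseline + 1):(n_baseline + n_stim),
       dose_sets = dose_sets,
       truth = list(amplitude = amplitude, tau_on_s = tau_on_s,
                    tau_off_s = tau_off_s, ec50_m = ec50_m, hill = hill,
                    top = top, f_base = f_base, background = background,
                    seed = seed))
}
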