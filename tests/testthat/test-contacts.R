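test_that("skeleton distances equal the exhaustive all-pairs oracle exactly", {
  set.seed(1)
  for (rep in 1:4) {
    d <- as.integer(sample(8:20, 3, replace = TRUE))
    sp <- 0.25
    cil <- array(FALSE, d); cil[cbind(sample(d[1], 6, TRUE), sample(d[2], 6, TRUE),
                                      sample(d[3], 6, TRUE))] <- TRUE
    tgt <- array(runif(prod(d)) < 0.05, d)
    if (!any(tgt)) tgt[1, 1, 1] <- TRUE
    skels <- structure(list(instances = list(which(cil, arr.ind = TRUE)),
                            coords = list(sweep(which(cil, arr.ind = TRUE) - 0.5, 2, sp, "*")),
                            radius = list(rep(sp, sum(cil))),
                            mask = cil, spacing = rep(sp, 3), dim = d),
                       class = "skeleton_set")
    dd <- distance_on_skeleton(skels, binary_mask(tgt, sp))
    oracle <- brute_force_edt(tgt, rep(sp, 3))
    expect_equal(dd$per_voxel[[1]], oracle[skels$instances[[1]]], tolerance = 1e-12)
    expect_equal(dd$minima, min(oracle[skels$instances[[1]]]), tolerance = 1e-12)
  }
})

test_that("a skeleton voxel on the target has distance exactly zero", {
  d <- c(6L, 6L, 6L)
  arr <- array(FALSE, d); arr[3, 3, 3] <- TRUE
  skels <- structure(list(instances = list(cbind(3L, 3L, 3L)),
                          coords = list(matrix(c(2.5, 2.5, 2.5) * 0.2, 1)),
                          radius = list(0.2), mask = arr,
                          spacing = rep(0.2, 3), dim = d),
                     class = "skeleton_set")
  dd <- distance_on_skeleton(skels, binary_mask(arr, 0.2))
  expect_equal(dd$minima, 0)
})

test_that("an empty target gives infinite distances with a warning", {
  d <- c(5L, 5L, 5L)
  skels <- structure(list(instances = list(cbind(2L, 2L, 2L)),
                          coords = list(matrix(0.3, 1, 3)),
                          radius = list(0.2), mask = array(TRUE, d),
                          spacing = rep(0.2, 3), dim = d),
                     class = "skeleton_set")
  expect_warning(dd <- distance_on_skeleton(skels, binary_mask(array(FALSE, d), 0.2)),
                 "empty target")
  expect_equal(dd$minima, Inf)
})

test_that("contact classification is inclusive at the 2-um cutoff", {
  tab <- data.frame(id = 1:4, excluded = FALSE,
                    min_axon_distance = c(0.5, 2.0, 2.0000001, 3.5),
                    contacting = NA)
  class(tab) <- c("cilium_table", "data.frame")
  out <- classify_contacts(tab, contact_params(contact_cutoff = 2.0))
  expect_equal(out$contacting, c(TRUE, TRUE, FALSE, FALSE))
})

test_that("planted distances 0.5/1.5/2.5/3.5 um classify as T/T/F/F", {
  tab <- data.frame(id = 1:4, excluded = FALSE,
                    min_axon_distance = c(0.5, 1.5, 2.5, 3.5), contacting = NA)
  class(tab) <- c("cilium_table", "data.frame")
  expect_equal(classify_contacts(tab)$contacting, c(TRUE, TRUE, FALSE, FALSE))
})

test_that("the contact count is monotone non-decreasing in the cutoff", {
  set.seed(2)
  tab <- data.frame(id = 1:30, excluded = FALSE,
                    min_axon_distance = runif(30, 0, 5), contacting = NA)
  class(tab) <- c("cilium_table", "data.frame")
  counts <- vapply(seq(0.5, 5, by = 0.5), function(ct)
    sum(classify_contacts(tab, contact_params(contact_cutoff = ct))$contacting),
    integer(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("filter_cilia excludes boundary and non-layer cilia, keeps the rest", {
  sc <- make_contact_scene(small_scene_params(seed = 1), channels = c("cilia", "nuclei"))
  tr <- sc$truth
  sk <- skeletonize_instances(binary_mask(tr$masks$cilia, tr$spacing))
  nuc <- binary_mask(tr$masks$nuclei, tr$spacing)
  layer <- select_layer(nuc, dilate_radius = 2.0)
  cen <- nucleus_centers(nuc)
  tab <- filter_cilia(sk, layer, cen)
  allp <- c(tr$cilium_paths, tr$scatter_paths, list(tr$boundary_path))
  mt <- match_to_paths(sk, allp)
  n_cil <- length(tr$cilium_paths)
  n_scatter <- length(tr$scatter_paths)
  expect_true(all(!tab$excluded[mt <= n_cil]))
  scatter_ids <- mt > n_cil & mt <= n_cil + n_scatter
  expect_true(all(tab$exclusion_reason[scatter_ids] == "non_layer_nucleus"))
  expect_true(all(tab$exclusion_reason[mt == n_cil + n_scatter + 1] == "boundary"))
  expect_true(all(is.na(tab$contacting[tab$excluded])))
})

test_that("puncta associate with axons by the inclusive 1-um rule", {
  d <- c(9L, 9L, 30L)
  sp <- 0.2
  inst <- cbind(z = rep(5L, 26), y = rep(5L, 26), x = 3:28)
  skels <- structure(list(instances = list(inst),
                          coords = list(sweep(inst - 0.5, 2, sp, "*")),
                          radius = list(rep(sp, 26)), mask = NULL,
                          spacing = rep(sp, 3), dim = d),
                     class = "skeleton_set")
  axis_y <- 4.5 * sp; axis_z <- 4.5 * sp
  pts <- rbind(c(axis_z + 0.3, axis_y, 2.0),    # 0.3 um off-axis
               c(axis_z + 1.4, axis_y, 2.0),    # 1.4 um off-axis
               c(axis_z, axis_y + 1.0, 3.5))    # exactly 1.0 um (at a voxel centre)
  ps <- associate_puncta(puncta_set(pts), skels)
  expect_equal(ps$association, c(TRUE, FALSE, TRUE))
})

test_that("association labels agree with exhaustive nearest-neighbour search", {
  set.seed(3)
  d <- c(12L, 12L, 12L); sp <- 0.25
  vox <- unique(cbind(sample(d[1], 15, TRUE), sample(d[2], 15, TRUE),
                      sample(d[3], 15, TRUE)))
  skels <- structure(list(instances = list(vox),
                          coords = list(sweep(vox - 0.5, 2, sp, "*")),
                          radius = list(rep(sp, nrow(vox))), mask = NULL,
                          spacing = rep(sp, 3), dim = d),
                     class = "skeleton_set")
  pts <- matrix(runif(30 * 3, 0, 3), 30)
  ps <- associate_puncta(puncta_set(pts), skels)
  sk_um <- skels$coords[[1]]
  oracle <- vapply(seq_len(30), function(i) {
    min(sqrt(colSums((t(sk_um) - pts[i, ])^2))) <= 1.0
  }, logical(1))
  expect_equal(ps$association, oracle)
})

test_that("percent_of reproduces the published worked examples exactly", {
  expect_identical(percent_of(426, 1209), 35L)
  expect_identical(percent_of(18, 27), 67L)
  expect_identical(percent_of(0, 10), 0L)
  expect_error(percent_of(1, 0), "total")
  expect_error(percent_of(-1, 10), "count")
})

test_that("ciliary receptor fraction matches a planted intensity split", {
  sp <- 0.3
  d <- c(20, 40, 40)
  cil <- array(FALSE, d); cil[8:12, 8:12, 5:35] <- TRUE
  rec <- array(0, d)
  rec[cil] <- 100                                   # inside: all supra-threshold
  out_idx <- which(!cil)[seq(1, 3000, by = 2)]
  rec[out_idx] <- 60                                # outside blob, supra-threshold
  s_in <- sum(rec[cil]); s_out <- sum(rec[out_idx])
  planted <- s_in / (s_in + s_out)
  fr <- ciliary_fraction(voxel_volume(rec, sp), binary_mask(cil, sp),
                         dilate_px = 0, total_threshold = 20)
  expect_equal(fr, planted, tolerance = 0.02)
  # all signal inside the (dilated) mask -> 1; none inside -> 0
  rec2 <- array(0, d); rec2[cil] <- 50
  expect_equal(ciliary_fraction(voxel_volume(rec2, sp), binary_mask(cil, sp)), 1)
  rec3 <- array(0, d); rec3[1, 1, 1] <- 50
  expect_equal(ciliary_fraction(voxel_volume(rec3, sp), binary_mask(cil, sp)), 0)
  expect_error(ciliary_fraction(voxel_volume(array(0, d), sp), binary_mask(cil, sp)),
               "zero total")
})

test_that("contact_summary counts and rounds like the headline figures", {
  tab <- data.frame(id = 1:6, excluded = c(FALSE, FALSE, FALSE, FALSE, FALSE, TRUE),
                    min_axon_distance = c(1, 1, 1, 3, 3, 1),
                    contacting = c(TRUE, TRUE, TRUE, FALSE, FALSE, NA))
  class(tab) <- c("cilium_table", "data.frame")
  s <- contact_summary(tab)
  expect_equal(s$n_analyzed, 5)
  expect_equal(s$n_contacting, 3)
  expect_equal(s$percent_contacting, 60L)
})
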