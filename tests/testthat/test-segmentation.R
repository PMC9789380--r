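test_that("Otsu threshold separates a well-split bimodal volume", {
  d <- c(5, 10, 10)
  set.seed(1)
  v <- array(10, d)
  hi <- sample(prod(d), round(0.4 * prod(d)))
  v[hi] <- 200
  thr <- otsu_threshold(v)
  expect_gt(thr, 10)
  expect_lte(thr, 200)
  mask <- otsu_mask(voxel_volume(v, 0.2))
  expect_equal(which(mask$values), sort(hi))
})

test_that("Otsu equals exhaustive between-class variance maximization", {
  set.seed(2)
  for (rep in 1:5) {
    v <- sample(0:255, 4000, replace = TRUE,
                prob = 0.6 * dnorm(0:255, 60, 20) + 0.4 * dnorm(0:255, 180, 30))
    expect_equal(otsu_threshold(v), brute_force_otsu(v))
  }
})

test_that("percentile-capped Otsu ignores outliers but masks all voxels", {
  set.seed(3)
  v <- c(rnorm(5000, 50, 5), rnorm(3000, 150, 10))
  out <- c(v, rep(5000, 400))            # 5% extreme outliers
  capped <- otsu_threshold(out, cap_percentile = 90)
  plain <- otsu_threshold(out)
  expect_lt(capped, 150)                 # sits between the two real modes
  expect_gt(capped, 50)
  expect_gt(plain, 200)                  # uncapped threshold is ruined
  # threshold computed on the capped values, applied to everything
  arr <- array(out[1:8000], c(20, 20, 20))
  m <- otsu_mask(voxel_volume(arr, 1), cap_percentile = 90)
  expect_equal(m$values, arr >= capped, ignore_attr = TRUE)
})

test_that("constant volumes are refused by both threshold methods", {
  expect_error(otsu_threshold(rep(7, 100)), "constant")
  expect_error(yen_threshold(rep(7, 100)), "constant")
})

test_that("Yen's threshold separates a clean bimodal sample", {
  set.seed(4)
  v <- c(rnorm(6000, 30, 5), rnorm(2000, 180, 15))
  thr <- yen_threshold(v)
  expect_gt(thr, 30)
  expect_lt(thr, 180)
  err <- mean(c(v[1:6000] >= thr, v[6001:8000] < thr))
  expect_lt(err, 0.02)
})

test_that("closing bridges sub-radius gaps and size filtering removes specks", {
  d <- c(9, 9, 30)
  arr <- array(FALSE, d)
  arr[4:6, 4:6, 2:12] <- TRUE            # fragment 1
  arr[4:6, 4:6, 14:26] <- TRUE           # fragment 2, 1-voxel gap at x = 13
  arr[1, 1, 29] <- TRUE                  # isolated speck
  m <- binary_mask(arr, 0.2)
  out <- close_and_filter(m, close_radius = 0.4, min_size = 0.05)
  lab <- label_components(out)
  expect_equal(max(lab), 1)              # fragments joined, speck removed
  expect_false(out$values[1, 1, 29])
})

test_that("size census after filtering matches brute-force component sizes", {
  set.seed(5)
  d <- c(12, 12, 12)
  arr <- array(runif(prod(d)) < 0.02, d) # random specks
  arr[4:9, 4:9, 4:9] <- TRUE             # one large block
  out <- close_and_filter(binary_mask(arr, 0.2), close_radius = 0,
                          min_size = 27 * 0.2^3)
  lab <- label_components(out)
  sizes <- tabulate(lab[lab > 0])
  expect_true(all(sizes * 0.2^3 >= 27 * 0.2^3))
  expect_equal(max(lab), 1)              # only the block survives
})

test_that("select_layer keeps the dense band and drops scattered nuclei", {
  sc <- make_contact_scene(small_scene_params(seed = 2), channels = "nuclei")
  tr <- sc$truth
  nuc <- binary_mask(tr$masks$nuclei, tr$spacing)
  layer <- select_layer(nuc, dilate_radius = 2.0)
  expect_equal(max(label_components(layer)), 1)   # always one component
  d <- tr$dim
  cen <- tr$nucleus_centers
  nv <- pmin(pmax(ceiling(sweep(cen, 2, tr$spacing, "/")), 1),
             matrix(d, nrow(cen), 3, byrow = TRUE))
  inlayer <- vapply(seq_len(nrow(nv)),
                    function(i) layer$values[nv[i, 1], nv[i, 2], nv[i, 3]],
                    logical(1))
  expect_true(all(inlayer[tr$nucleus_in_band]))
  expect_false(any(inlayer[!tr$nucleus_in_band]))
})

test_that("select_layer of a single nucleus returns that nucleus dilated", {
  arr <- array(FALSE, c(15, 15, 15))
  arr[6:10, 6:10, 6:10] <- TRUE
  out <- select_layer(binary_mask(arr, 0.2), dilate_radius = 0.4)
  expect_true(all(out$values[arr]))
  expect_error(select_layer(binary_mask(array(FALSE, c(3, 3, 3)), 0.2)), "empty")
})

test_that("nucleus_centers finds sphere centres within one voxel", {
  sp <- 0.2
  d <- c(30, 30, 30)
  arr <- array(0, d)
  ctr <- c(3.0, 3.0, 3.0)
  arr <- ciliaxis:::raster_sphere(arr, rep(sp, 3), ctr, 2.0)
  cen <- nucleus_centers(binary_mask(arr > 0, sp), erode_radius = 0.5)
  expect_equal(nrow(cen), 1)
  expect_lt(max(abs(cen[1, ] - ctr)), sp)
})

test_that("distance-transform splitting separates overlapping nuclei", {
  sp <- 0.2
  d <- c(30, 30, 50)
  arr <- array(0, d)
  c1 <- c(3, 3, 3.0); c2 <- c(3, 3, 6.6)   # spheres r = 2 um, overlap 0.2 r
  arr <- ciliaxis:::raster_sphere(arr, rep(sp, 3), c1, 2.0)
  arr <- ciliaxis:::raster_sphere(arr, rep(sp, 3), c2, 2.0)
  cen <- nucleus_centers(binary_mask(arr > 0, sp), erode_radius = 0.4)
  expect_equal(nrow(cen), 2)
  err <- pmin(sqrt(colSums((t(cen) - c1)^2)), sqrt(colSums((t(cen) - c2)^2)))
  expect_true(all(err <= 2 * sp))
})

test_that("nucleus count matches planted count on a generated scene", {
  sc <- make_contact_scene(small_scene_params(seed = 4), channels = "nuclei")
  tr <- sc$truth
  cen <- nucleus_centers(binary_mask(tr$masks$nuclei, tr$spacing))
  expect_equal(nrow(cen), nrow(tr$nucleus_centers))
})

test_that("an empty mask after erosion yields an empty centre list with a warning", {
  arr <- array(FALSE, c(8, 8, 8)); arr[4, 4, 4] <- TRUE
  expect_warning(cen <- nucleus_centers(binary_mask(arr, 0.2), erode_radius = 1),
                 "empty")
  expect_equal(nrow(cen), 0)
})
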