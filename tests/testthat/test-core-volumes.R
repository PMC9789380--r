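test_that("voxel_volume enforces its grid and value contracts", {
  expect_s3_class(voxel_volume(array(0, c(2, 3, 4)), 0.2), "voxel_volume")
  expect_error(voxel_volume(matrix(0, 2, 2), 0.2), "3D")
  expect_error(voxel_volume(array(0, c(2, 2, 2)), c(-1, 1, 1)), "positive")
  expect_error(voxel_volume(array(NA_real_, c(2, 2, 2)), 0.2), "finite")
  expect_error(voxel_volume(array(0.5, c(2, 2, 2)), 0.2, counts = TRUE), "integer")
  expect_error(multichannel_volume(list(a = voxel_volume(array(0, c(2, 2, 2)), 0.2),
                                        b = voxel_volume(array(0, c(2, 2, 3)), 0.2))),
               "share")
})

test_that("resample_isotropic is the identity on an already-isotropic grid", {
  v <- voxel_volume(array(runif(4 * 5 * 6), c(4, 5, 6)), 0.189)
  expect_identical(resample_isotropic(v, 0.189)$values, v$values)
})

test_that("resampling 41x41x189 nm data to 189 nm downsamples x,y and keeps extent", {
  d <- c(6, 60, 60)
  v <- voxel_volume(array(runif(prod(d)), d), c(0.189, 0.041, 0.041))
  out <- resample_isotropic(v, 0.189, downsample_only = TRUE)
  expect_equal(out$spacing, rep(0.189, 3))
  expect_equal(dim(out$values)[1], 6)              # z untouched
  expect_equal(dim(out$values)[2], round(60 * 0.041 / 0.189))  # ~4.6x fewer
  # physical extent preserved within one voxel per axis
  expect_true(all(abs(dim(out$values) * 0.189 - d * v$spacing) <= 0.189))
})

test_that("resampling a linear ramp reproduces the ramp at the new coordinates", {
  d <- c(4, 4, 40)
  sp <- 0.1
  ramp <- array(rep((seq_len(d[3]) - 0.5) * sp, each = d[1] * d[2]), d)
  v <- voxel_volume(ramp, sp)
  out <- resample_isotropic(v, 0.2)
  # oracle: the ramp value at each new voxel-centre x coordinate
  xs <- (seq_len(dim(out$values)[3]) - 0.5) * 0.2
  expect_equal(as.vector(out$values[2, 2, ]), xs, tolerance = 1e-10)
})

test_that("resampling preserves integrated intensity for smooth fields", {
  d <- c(16, 16, 16)
  co <- (seq_len(16) - 0.5) / 16
  arr <- outer(outer(sin(pi * co), sin(pi * co)), sin(pi * co)) + 2
  v <- voxel_volume(array(arr, d), 0.1)
  out <- resample_isotropic(v, 0.16)
  before <- sum(v$values) * prod(v$spacing)
  after <- sum(out$values) * prod(out$spacing)
  expect_lt(abs(after - before) / before, 0.01)
})

test_that("linear unmixing recovers abundances (closed-form 2x2 oracle)", {
  M <- rbind(c(0.9, 0.2), c(0.1, 0.8))
  d <- c(4, 5, 6)
  set.seed(1)
  a1 <- array(runif(prod(d), 0, 100), d)
  a2 <- array(runif(prod(d), 0, 100), d)
  y1 <- M[1, 1] * a1 + M[1, 2] * a2
  y2 <- M[2, 1] * a1 + M[2, 2] * a2
  mc <- multichannel_volume(list(det1 = voxel_volume(y1, 0.2),
                                 det2 = voxel_volume(y2, 0.2)))
  out <- linear_unmix(mc, mixing_matrix(M))
  # oracle: explicit 2x2 inverse
  inv <- solve(M)
  expect_equal(out$channels[[1]]$values, inv[1, 1] * y1 + inv[1, 2] * y2,
               tolerance = 1e-10)
  expect_lt(max(abs(out$channels[[2]]$values - a2)) / max(a2), 1e-10)
})

test_that("unmixing with the identity matrix returns the input; zeros stay zero", {
  d <- c(3, 3, 3)
  arr <- array(runif(prod(d)), d)
  arr[1, 1, 1] <- 0
  mc <- multichannel_volume(list(a = voxel_volume(arr, 0.2),
                                 b = voxel_volume(array(0, d), 0.2)))
  out <- linear_unmix(mc, mixing_matrix(diag(2)))
  expect_equal(out$channels[[1]]$values, arr, tolerance = 1e-12)
  expect_equal(out$channels[[2]]$values, array(0, d))
})

test_that("unmix then remix reproduces the input to numerical precision", {
  M <- rbind(c(0.7, 0.3), c(0.2, 0.9))
  d <- c(3, 4, 5)
  set.seed(2)
  y <- lapply(1:2, function(i) array(runif(prod(d), 10, 50), d))
  # make the observation consistent with non-negative abundances
  a <- lapply(1:2, function(i) array(runif(prod(d), 0, 10), d))
  y <- list(M[1, 1] * a[[1]] + M[1, 2] * a[[2]],
            M[2, 1] * a[[1]] + M[2, 2] * a[[2]])
  mc <- multichannel_volume(list(d1 = voxel_volume(y[[1]], 1), d2 = voxel_volume(y[[2]], 1)))
  ab <- linear_unmix(mc, mixing_matrix(M))
  remix1 <- M[1, 1] * ab$channels[[1]]$values + M[1, 2] * ab$channels[[2]]$values
  expect_equal(remix1, y[[1]], tolerance = 1e-9)
})

test_that("ill-conditioned or mismatched mixing matrices are refused", {
  expect_error(mixing_matrix(rbind(c(1, 1), c(1, 1 + 1e-14))), "ill conditioned")
  expect_error(mixing_matrix(matrix(1, 1, 2)), "overdetermined")
  mc <- multichannel_volume(list(a = voxel_volume(array(1, c(2, 2, 2)), 1)))
  expect_error(linear_unmix(mc, mixing_matrix(diag(2))), "does not match")
})

test_that("flim_split gates by arrival time and conserves photons exactly", {
  d <- c(4, 4, 4)
  cnt <- array(rpois(prod(d), 50), d)
  # all arrivals at the dye peak -> everything is signal
  fv <- flim_volume(cnt, array(2.3, d), 0.3)
  sp <- flim_split(fv, gate = 1.0)
  expect_equal(sp$signal$values, cnt)
  expect_equal(sum(sp$background$values), 0)
  # all arrivals at the autofluorescence peak -> everything is background
  fv2 <- flim_volume(cnt, array(0.3, d), 0.3)
  sp2 <- flim_split(fv2, gate = 1.0)
  expect_equal(sum(sp2$signal$values), 0)
  expect_equal(sp2$background$values, cnt)
})

test_that("flim_split reproduces known population labels voxel by voxel", {
  set.seed(3)
  d <- c(5, 6, 7)
  cnt <- array(rpois(prod(d), 30) + 1L, d)
  lab <- array(runif(prod(d)) < 0.4, d)     # TRUE = dye population
  arr <- array(0.3, d); arr[lab] <- 2.3
  sp <- flim_split(flim_volume(cnt, arr, 0.3), gate = 1.0)
  expect_equal(sp$signal$values > 0, lab)
  expect_equal(sp$signal$values + sp$background$values, cnt)  # exact conservation
})

test_that("volumes and masks survive a TIFF + sidecar round trip", {
  dir <- withr::local_tempdir()
  v <- voxel_volume(array(runif(3 * 4 * 5, 0, 1000), c(3, 4, 5)),
                    c(0.3, 0.1, 0.1), channel = "test")
  p <- file.path(dir, "v.tif")
  write_volume(v, p)
  back <- read_volume(p)
  expect_equal(back$values, v$values, tolerance = 1e-6)
  expect_equal(back$spacing, v$spacing)
  expect_equal(back$channel, "test")
  m <- binary_mask(array(runif(60) > 0.5, c(3, 4, 5)), 0.2)
  pm <- file.path(dir, "m.tif")
  write_mask(m, pm)
  expect_equal(read_mask(pm)$values, m$values)
  # spacing metadata is required, never defaulted
  file.remove(paste0(p, ".json"))
  expect_error(read_volume(p), "sidecar")
})
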