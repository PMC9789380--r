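test_that("dF/F0 arithmetic: baseline, background and the constant case", {
  tr <- sensor_trace(1:20, rep(10, 20))
  out <- delta_f_over_f(tr, 1:5)
  expect_equal(out$dff, rep(0, 20))
  # F jumps 10 -> 12 with background 2: F0 = 8, post-jump dff = 0.25
  tr2 <- sensor_trace(1:20, c(rep(10, 10), rep(12, 10)))
  out2 <- delta_f_over_f(tr2, 1:10, background = 2)
  expect_equal(out2$F0, 8)
  expect_equal(out2$dff[11:20], rep(0.25, 10))
  expect_error(delta_f_over_f(tr, integer(0)), "empty")
  expect_error(delta_f_over_f(sensor_trace(1:5, rep(1, 5)), 1:2, background = 2),
               "F0 <= 0")
})

test_that("dF/F0 is invariant under joint scaling of F and background", {
  F <- c(rep(50, 10), rep(65, 20))
  a <- delta_f_over_f(sensor_trace(1:30, F), 1:10, background = 10)
  b <- delta_f_over_f(sensor_trace(1:30, F * 7), 1:10, background = 70)
  expect_equal(a$dff, b$dff, tolerance = 1e-12)
})

test_that("the hard low-pass removes fast components and keeps slow ones", {
  rate <- 4; t <- seq(0, 60 - 1 / rate, by = 1 / rate)
  fast <- sensor_trace(t, sin(2 * pi * 0.5 * t))
  out <- lowpass_fourier(fast, cutoff = 0.2, rate = rate)
  expect_lt(max(abs(out$F)), 1e-6)                  # 0.5 Hz fully suppressed
  slow <- sensor_trace(t, sin(2 * pi * 0.05 * t))
  out2 <- lowpass_fourier(slow, cutoff = 0.2, rate = rate)
  expect_lt(max(abs(out2$F - slow$F)) / max(abs(slow$F)), 0.01)
})

test_that("low-pass preserves the mean exactly and is idempotent", {
  set.seed(1)
  rate <- 5; t <- seq(0, 39.8, by = 1 / rate)
  tr <- sensor_trace(t, rnorm(length(t), 3))
  f1 <- lowpass_fourier(tr, 0.3, rate)
  expect_equal(mean(f1$F), mean(tr$F), tolerance = 1e-12)
  f2 <- lowpass_fourier(f1, 0.3, rate)
  expect_equal(f2$F, f1$F, tolerance = 1e-10)
  expect_error(lowpass_fourier(sensor_trace(c(1, 2, 4), 1:3), 0.1), "non-uniform")
  expect_error(lowpass_fourier(tr, 3, rate), "cutoff")
})

test_that("response metrics extract the peak and mean over the stimulus window", {
  dff <- rep(0, 40)
  dff[11:20] <- c(seq(0.03, 0.15, length.out = 5), seq(0.12, 0, length.out = 5))
  tr <- sensor_trace(1:40, 100 * (1 + dff))
  tr <- delta_f_over_f(tr, 1:10)
  m <- response_metrics(tr, 11:20)
  expect_equal(m$peak_dff, 0.15, tolerance = 1e-9)
  # boxcar of height 0.08 covering the window -> mean 0.08
  tr2 <- delta_f_over_f(sensor_trace(1:40, 100 * (1 + c(rep(0, 10), rep(0.08, 10),
                                                        rep(0, 20)))), 1:10)
  expect_equal(response_metrics(tr2, 11:20)$mean_dff, 0.08, tolerance = 1e-9)
  expect_equal(response_metrics(tr2, 25:30)$peak_dff, 0, tolerance = 1e-9)
})

test_that("noiseless Hill data recover the generator EC50 to 0.1%", {
  mt <- make_traces(seed = 1)
  for (k in seq_along(mt$dose_sets)) {
    fit <- hill_fit(mt$dose_sets[[k]]$conc, mt$dose_sets[[k]]$resp)
    expect_lt(abs(fit$fit["EC50"] - mt$truth$ec50_m[k]) / mt$truth$ec50_m[k], 1e-3)
    expect_equal(unname(fit$fit["hill"]), 1, tolerance = 1e-3)
  }
})

test_that("EC50 under 5% multiplicative noise has a median within 10% of truth", {
  set.seed(2)
  ec <- 84e-9
  conc <- 10^seq(log10(ec) - 2, log10(ec) + 2, length.out = 8)
  clean <- 0.3 / (1 + ec / conc)
  est <- replicate(40, {
    resp <- clean * (1 + rnorm(8, 0, 0.05))
    suppressWarnings(hill_fit(conc, resp)$fit[["EC50"]])
  })
  expect_lt(abs(stats::median(est) - ec) / ec, 0.10)
})

test_that("noiseless exponential kinetics recover tau within 1%", {
  mt <- make_traces(seed = 3)
  tr <- mt$trace
  on <- sensor_trace(tr$t[mt$stim_window], tr$F[mt$stim_window])
  off_w <- (max(mt$stim_window) + 1):length(tr$t)
  off <- sensor_trace(tr$t[off_w], tr$F[off_w])
  expect_lt(abs(exp_kinetics_fit(on, "on")$tau - 0.19) / 0.19, 0.01)
  expect_lt(abs(exp_kinetics_fit(off, "off")$tau - 8.46) / 8.46, 0.01)
})

test_that("noisy decays at SNR 10 give a median tau within 5% over replicates", {
  set.seed(4)
  tau <- 8.46
  t <- seq(0, 30, by = 0.2)
  est <- replicate(40, {
    y <- 10 * exp(-t / tau) + 2 + rnorm(length(t), 0, 1)
    suppressWarnings(exp_kinetics_fit(sensor_trace(t, y), "off")$tau)
  })
  expect_lt(abs(stats::median(est) - tau) / tau, 0.05)
})

test_that("a short trace triggers the coverage warning", {
  t <- seq(0, 1, by = 0.05)
  y <- 5 * exp(-t / 2) + 1
  expect_warning(exp_kinetics_fit(sensor_trace(t, y), "off"), "time constants")
})

test_that("temporal averaging by 2 halves the frame count pairwise", {
  tr <- sensor_trace(1:10, c(1, 3, 5, 7, 2, 4, 6, 8, 10, 12))
  out <- temporal_average2(tr)
  expect_equal(length(out$t), 5)
  expect_equal(out$F, c(2, 6, 3, 7, 11))
})

test_that("roi_trace averages a disk at the contact site per frame", {
  fr <- array(0, c(20, 20, 3))
  fr[9:11, 9:11, 2] <- 9
  tr <- roi_trace(fr, center_yx = c(10, 10), radius_px = 1.2)
  expect_equal(tr$F[1], 0)
  expect_gt(tr$F[2], 0)
})

test_that("the FRET ratio is the masked sensitized/donor quotient", {
  nz <- 3; ny <- 40; nx <- 40; nt <- 20
  don <- array(0, c(nz, ny, nx, nt)); sen <- don
  for (k in seq_len(nt)) {
    dk <- matrix(0, ny, nx); sk <- matrix(0, ny, nx)
    dk[15:25, 15:25] <- 100
    sk[15:25, 15:25] <- 50
    don[2, , , k] <- dk; sen[2, , , k] <- sk
  }
  bg <- matrix(FALSE, ny, nx); bg[1:5, 1:5] <- TRUE
  fr <- fret_ratio_series(don, sen, bg, ball_radius = 8)
  expect_equal(fr$ratio, rep(0.5, nt), tolerance = 1e-9)
})

test_that("planted additive background cancels after bg-region subtraction", {
  nz <- 2; ny <- 30; nx <- 30; nt <- 8
  don <- array(10, c(nz, ny, nx, nt)); sen <- array(10, c(nz, ny, nx, nt))
  for (k in seq_len(nt)) {
    don[2, 12:18, 12:18, k] <- 110      # structure + background 10
    sen[2, 12:18, 12:18, k] <- 60
  }
  bg <- matrix(FALSE, ny, nx); bg[1:4, 1:4] <- TRUE
  fr <- fret_ratio_series(don, sen, bg, ball_radius = 6)
  expect_equal(fr$ratio, rep(0.5, nt), tolerance = 1e-9)
})

test_that("a step increase in sensitized emission reads out as dR/R0", {
  nz <- 2; ny <- 30; nx <- 30; nt <- 20
  don <- array(0, c(nz, ny, nx, nt)); sen <- don
  for (k in seq_len(nt)) {
    don[2, 12:18, 12:18, k] <- 100
    sen[2, 12:18, 12:18, k] <- if (k > 10) 60 else 50
  }
  bg <- matrix(FALSE, ny, nx); bg[1:4, 1:4] <- TRUE
  fr <- fret_ratio_series(don, sen, bg, ball_radius = 6, baseline_frames = 1:10)
  expect_equal(fr$drr[11:20], rep(0.2, 10), tolerance = 1e-9)
})

test_that("the FRET ratio is invariant under joint rescaling of both channels", {
  nz <- 2; ny <- 24; nx <- 24; nt <- 5
  set.seed(5)
  don <- array(0, c(nz, ny, nx, nt)); sen <- don
  for (k in seq_len(nt)) {
    base <- matrix(0, ny, nx); base[10:16, 10:16] <- 80 + runif(49, 0, 10)
    don[1, , , k] <- base
    sen[1, , , k] <- base * 0.6
  }
  bg <- matrix(FALSE, ny, nx); bg[1:4, 1:4] <- TRUE
  f1 <- fret_ratio_series(don, sen, bg, ball_radius = 5)
  f2 <- fret_ratio_series(don * 3, sen * 3, bg, ball_radius = 5)
  expect_equal(f1$ratio, f2$ratio, tolerance = 1e-9)
})

test_that("two-component decay fits recover the quenched fraction", {
  tb <- seq(0.05, 12, by = 0.1)
  m <- lifetime_model()
  pure_u <- flim_fraction_fit(tb, exp(-tb / 2.7), m)
  expect_equal(pure_u$model$quenched_fraction, 0, tolerance = 1e-9)
  expect_equal(pure_u$mean_lifetime_ns, 2.7, tolerance = 1e-9)
  pure_q <- flim_fraction_fit(tb, exp(-tb / 1.3), m)
  expect_equal(pure_q$model$quenched_fraction, 1, tolerance = 1e-9)
  mix <- flim_fraction_fit(tb, 0.5 * exp(-tb / 1.3) + 0.5 * exp(-tb / 2.7), m)
  expect_equal(mix$model$quenched_fraction, 0.5, tolerance = 1e-6)
  expect_equal(mix$mean_lifetime_ns, 2.0, tolerance = 1e-6)
})

test_that("mean lifetime decreases monotonically with quenched fraction", {
  tb <- seq(0.05, 12, by = 0.1)
  fr <- seq(0, 1, by = 0.2)
  mls <- vapply(fr, function(f)
    flim_fraction_fit(tb, f * exp(-tb / 1.3) + (1 - f) * exp(-tb / 2.7))$mean_lifetime_ns,
    numeric(1))
  expect_true(all(diff(mls) < 0))
})

test_that("degenerate decays and short histograms are refused", {
  expect_error(flim_fraction_fit(seq(0.1, 6, length.out = 5), rep(1, 5)), ">= 10")
  tb <- seq(0.05, 12, by = 0.1)
  cnt <- rep(0, length(tb)); cnt[1] <- 100
  expect_error(flim_fraction_fit(tb, cnt), "degenerate")
})

test_that("alpha-sample modes are recovered within 2% of the closed form", {
  set.seed(6)
  x <- ralpha(1e5, shape = 3, location = 0.5, scale = 2)
  fp <- ciliaxis:::fit_alpha(x)
  est <- alpha_mode(fp[["shape"]], fp[["location"]], fp[["scale"]])
  truth <- alpha_mode(3, 0.5, 2)
  expect_equal(truth, 0.5 + 2 * (sqrt(17) - 3) / 4)   # closed form
  expect_lt(abs(est - truth) / truth, 0.02)
})

test_that("the analytic alpha mode matches a numeric density maximizer", {
  for (a in c(1.5, 3, 6)) {
    grid <- seq(1e-4, 3, length.out = 20000)
    num <- grid[which.max(dalpha(grid, a))]
    expect_equal(alpha_mode(a), num, tolerance = 1e-3)
  }
})

test_that("flim_cilium_mode filters low counts and hits the planted mode", {
  fs <- make_flim_scene(seed = 2)
  ls <- flim_cilium_mode(fs$flim, fs$mask)
  expect_lt(abs(ls$mode_ns - fs$truth$mode) / fs$truth$mode, 0.05)
  # adversarial lifetimes on sub-filter voxels change nothing
  fs2 <- make_flim_scene(seed = 2, adversarial_low = TRUE)
  ls2 <- flim_cilium_mode(fs2$flim, fs2$mask)
  expect_equal(ls2$mode_ns, ls$mode_ns, tolerance = 1e-9)
})

test_that("a zero-variance lifetime sample takes the degenerate branch", {
  d <- c(4, 4, 4)
  cnt <- array(100L, d)
  fv <- flim_volume(cnt, array(2.0, d), 0.3)
  ls <- flim_cilium_mode(fv, binary_mask(array(TRUE, d), 0.3))
  expect_equal(ls$mode_ns, 2.0)
  expect_true(ls$degenerate)
})

test_that("a quenched/unquenched mixture has its mode inside [1.3, 2.7] ns", {
  fs <- make_flim_scene(seed = 3, lifetimes = "mixture", mixture_fraction = 0.5)
  ls <- flim_cilium_mode(fs$flim, fs$mask)
  expect_gte(ls$mode_ns, 1.3)
  expect_lte(ls$mode_ns, 2.7)
})

test_that("too few usable voxels is a refusal, not a guess", {
  d <- c(4, 4, 4)
  cnt <- array(10L, d); cnt[1:3] <- 100L
  fv <- flim_volume(cnt, array(2, d) + array(runif(prod(d)), d), 0.3)
  expect_error(flim_cilium_mode(fv, binary_mask(array(TRUE, d), 0.3)), "usable")
})
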