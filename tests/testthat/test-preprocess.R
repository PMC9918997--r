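# Filtering, EMG envelope extraction and normalization, resampling, and
# cross-correlation synchronization.

test_that("Butterworth filter honours DC, cutoff and stopband contracts", {
  fs <- 128
  t <- seq(0, 8, by = 1 / fs)
  lp <- filter_spec("low", 4, 10)
  # DC gain 1: constants pass unchanged
  expect_equal(butterworth_filter(rep(3.7, length(t)), fs, lp),
               rep(3.7, length(t)), tolerance = 1e-9)
  # unit sine at the cutoff: zero-phase amplitude 0.5 (squared -3 dB)
  x <- sin(2 * pi * 10 * t)
  y <- butterworth_filter(x, fs, lp)
  core <- y[t > 2 & t < 6] # steady state away from the edges
  amp <- (max(core) - min(core)) / 2
  expect_equal(amp, 0.5, tolerance = 0.02)
  # passband: 2 Hz sine preserved within 2%
  x2 <- sin(2 * pi * 2 * t)
  y2 <- butterworth_filter(x2, fs, lp)
  expect_equal((max(y2[t > 2 & t < 6]) - min(y2[t > 2 & t < 6])) / 2, 1,
               tolerance = 0.02)
  # high-pass rejects DC essentially exactly
  hp <- filter_spec("high", 4, 20)
  expect_lt(max(abs(butterworth_filter(rep(5, 4097), 1024, hp))), 1e-6)
  # configuration errors
  expect_error(butterworth_filter(rnorm(100), 16, lp, "gyro_x"),
               "Nyquist.*gyro_x")
  expect_error(butterworth_filter(rnorm(5), fs, lp), "too short")
})

test_that("zero-phase filtering introduces no group delay", {
  fs <- 128
  t <- seq(0, 4, by = 1 / fs)
  # symmetric input about its midpoint -> symmetric output
  x <- exp(-0.5 * ((t - 2) / 0.3)^2)
  y <- butterworth_filter(x, fs, filter_spec("low", 4, 6))
  expect_equal(y, rev(y), tolerance = 1e-6)
  expect_equal(which.max(y), which.max(x))
})

test_that("EMG pipeline recovers rectified-sine plateaus and normalizes", {
  fs <- 1024
  t <- seq(0, 6, by = 1 / fs)
  # zero in, zero out
  grid <- seq(0.5, 5.5, by = 1 / 25)
  expect_equal(process_emg(numeric(length(t)), fs, reference_value = 1,
                           grid = grid), rep(0, length(grid)))
  # 50 Hz sinusoid of amplitude A: envelope plateau ~ 2A/pi / reference
  A <- 1.8
  x <- A * sin(2 * pi * 50 * t)
  env <- process_emg(x, fs, reference_value = 2, grid = grid)
  plateau <- env[grid > 1.5 & grid < 4.5]
  expect_equal(mean(plateau), (2 * A / pi) / 2, tolerance = 0.1 * 2 * A / pi)
  expect_true(all(env >= 0))
  expect_error(process_emg(x, fs, reference_value = 0, grid = grid),
               "positive")
})

test_that("EMG reference normalizes the static posture to ~1", {
  fs <- 1024
  t <- seq(0, 6, by = 1 / fs)
  set.seed(4)
  x <- 0.8 * rnorm(length(t)) # amplitude-stationary surrogate recording
  ref <- compute_emg_reference(x, fs, muscle = "deltoid_medial")
  expect_gt(ref$reference_value, 0)
  env <- emg_envelope(x, fs) / ref$reference_value
  idx <- seq(round(0.2 * length(t)), round(0.8 * length(t)))
  expect_equal(mean(env[idx]), 1, tolerance = 0.05)
  expect_error(compute_emg_reference(x, fs, window_s = c(5, 9)), "outside")
  # constant envelope c over the window gives reference c
  expect_error(compute_emg_reference(rep(0, length(t)), fs), "non-positive")
})

test_that("IMU and SJRF processing preserve passband content at 25 Hz", {
  fs <- 128
  t <- seq(0, 6, by = 1 / fs)
  grid <- seq(0.5, 5.5, by = 1 / 25)
  # constant channel stays constant
  const <- process_imu(matrix(2.5, length(t), 1), fs, grid, time = t)
  expect_equal(as.numeric(const), rep(2.5, length(grid)), tolerance = 1e-6)
  # 2 Hz sine: amplitude preserved within 2%
  x <- matrix(sin(2 * pi * 2 * t), ncol = 1)
  y <- as.numeric(process_imu(x, fs, grid, time = t))
  expect_equal((max(y) - min(y)) / 2, 1, tolerance = 0.02)
  # sample-count contract of the shared grid
  expect_equal(length(grid), floor(5 * 25) + 1)

  # SJRF: 1 Hz preserved, 12 Hz crushed
  ts100 <- seq(0, 6, by = 1 / 100)
  y1 <- process_sjrf(cbind(sin(2 * pi * 1 * ts100), 0, 0), 100, grid,
                     time = ts100)
  expect_equal((max(y1[, 1]) - min(y1[, 1])) / 2, 1, tolerance = 0.02)
  y12 <- process_sjrf(cbind(10, sin(2 * pi * 12 * ts100), 0), 100, grid,
                      time = ts100)
  core <- y12[grid > 1.5 & grid < 4.5, 2]
  expect_lt((max(core) - min(core)) / 2, 0.05)
  expect_equal(y12[, 1], rep(10, length(grid)), tolerance = 1e-6)
})

test_that("resampling onto the same grid is the identity", {
  grid <- seq(0, 4, by = 1 / 25)
  X <- cbind(sin(grid), cos(2 * grid))
  expect_equal(sjrfest:::resample_linear(grid, X, grid), X, tolerance = 1e-9)
})

test_that("injected stream offsets are recovered within one native sample", {
  co <- smoke_cohort(n_participants = 2, noise_sd = 1, seed = 8,
                     duration_scale = 0.25)
  errs <- c()
  for (k in c(1, 7, 12, 19, 26, 33)) {
    rec <- co$recordings[[k]]
    est <- synchronize_streams(rec)
    errs <- c(errs, abs(est - rec$stream_offsets_s[names(est)]))
  }
  expect_lt(max(errs), 1 / 128)
})

test_that("streams without a fiducial trigger the low-correlation warning", {
  co <- smoke_cohort(n_participants = 1, noise_sd = 1, seed = 8,
                     duration_scale = 0.25)
  rec <- co$recordings[[1]]
  # replace one stream with pure noise: no shared feature to lock onto
  set.seed(1)
  rec$emg$deltoid_medial$data[, 1] <- rnorm(nrow(rec$emg$deltoid_medial$data))
  expect_warning(est <- synchronize_streams(rec), "deltoid_medial")
  expect_identical(unname(est["deltoid_medial"]), 0)
})

test_that("aligned trials share one exact 25 Hz grid and are complete", {
  co <- smoke_cohort(n_participants = 1, noise_sd = 1, seed = 8,
                     duration_scale = 0.25)
  al <- align_cohort(co)
  a <- al$aligned[[1]]
  expect_s3_class(a, "sjrf_aligned")
  expect_identical(ncol(a), 36L) # time + 30 IMU + 2 EMG + 3 SJRF
  expect_false(anyNA(a))
  # shared grid: multiples of 1/25, identical for every stream by construction
  expect_equal(a$time_s, round(a$time_s * 25) / 25, tolerance = 1e-12)
  expect_equal(diff(a$time_s), rep(1 / 25, nrow(a) - 1), tolerance = 1e-12)
  # EMG non-negative after processing
  expect_true(all(a$emg_biceps_long_head >= 0))
  expect_true(all(a$emg_deltoid_medial >= 0))
  # fiducial burst and lead-in cropped: only the activity window remains
  dur <- co$recordings[[1]]$duration_s
  expect_lt(nrow(a), dur * 25 + 5)
  expect_gt(nrow(a), dur * 25 - 30)
})

test_that("alignment undoes the injected clock offsets", {
  # same trial generated with and without offsets must align to near-equal
  # force targets (the SJRF clock is the reference)
  tr <- sample_traits(1, 0.3, seed = 5)
  tpl <- activity_templates(0.3)$propulsion_056
  rec_off <- generate_trial(tr, tpl, 1, noise_sd = 0, seed = 6,
                            max_offset_s = 0.4)
  rec_zero <- generate_trial(tr, tpl, 1, noise_sd = 0, seed = 6,
                             max_offset_s = 0)
  refs <- list(
    biceps_long_head = list(reference_value = 1),
    deltoid_medial = list(reference_value = 1))
  a_off <- align_trial(rec_off, refs)
  a_zero <- align_trial(rec_zero, refs)
  n <- min(nrow(a_off), nrow(a_zero))
  # compare a mid-trial stretch of an offset-bearing IMU channel
  col <- "lower_arm_acc_x"
  i <- seq(10, n - 10)
  expect_gt(cor(a_off[[col]][i], a_zero[[col]][i]), 0.999)
})
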