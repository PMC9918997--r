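# Synthetic cohort generator: trait distributions, generative
# self-consistency, activity dynamics, subtrial accounting, determinism and
# the file round-trip.

test_that("trait sampling is seeded, spread scales with heterogeneity", {
  # zero heterogeneity collapses every participant onto the baseline
  for (id in c(1, 4, 9)) {
    tr <- sample_traits(id, heterogeneity = 0, seed = 7)
    expect_identical(tr$body_mass_scale, 1)
    expect_equal(unname(tr$emg_gain), c(1, 1))
    expect_equal(tr$kinematic_offset, c(0, 0, 0))
  }
  # seed determinism
  expect_identical(sample_traits(1, 0.3, seed = 7), sample_traits(1, 0.3, seed = 7))
  expect_false(identical(sample_traits(1, 0.3, 7), sample_traits(2, 0.3, 7)))

  # Monte-Carlo check of the documented body-mass spread (SD = 0.35 * h)
  h <- 0.3
  draws <- vapply(seq_len(1000), function(i) {
    sample_traits(i, heterogeneity = h, seed = 123)$body_mass_scale
  }, 0)
  expect_lt(abs(sd(draws) - 0.35 * h) / (0.35 * h), 0.2)

  # heterogeneity monotonicity: between-participant variance non-decreasing
  spread <- vapply(c(0, 0.15, 0.3, 0.6), function(h) {
    stats::var(vapply(1:60, function(i) {
      sample_traits(i, h, seed = 5)$body_mass_scale
    }, 0))
  }, 0)
  expect_true(all(diff(spread) >= 0))
})

test_that("subtrial accounting matches the splitting scheme", {
  tpl <- activity_templates()
  expect_length(tpl, 8)
  expect_identical(sum(vapply(tpl, `[[`, 0L, "n_subtrials")), 19L)
  # the three treadmill conditions contribute two subtrials each
  expect_identical(tpl$propulsion_056$n_subtrials, 2L)
  expect_identical(tpl$weight_relief$n_subtrials, 2L)
  expect_identical(tpl$weight_relief$subtrial_duration_s, 10)
})

test_that("generated recordings have the documented stream layout", {
  co <- smoke_cohort()
  rec <- co$recordings[[1]]
  expect_named(rec$imu, c("lower_arm", "upper_arm", "thorax", "wc_frame",
                          "wc_wheel"))
  expect_named(rec$emg, c("biceps_long_head", "deltoid_medial"))
  for (s in rec$imu) {
    expect_identical(ncol(s$data), 6L)
    expect_identical(s$fs, 128)
  }
  for (s in rec$emg) expect_identical(s$fs, 1024)
  expect_identical(rec$sjrf$fs, 100)
  expect_true(all(is.finite(rec$sjrf$data)))
  # hidden offsets present, bounded, reference stream at zero
  expect_identical(unname(rec$stream_offsets_s["upper_arm"]), 0)
  expect_true(all(abs(rec$stream_offsets_s) <= 0.5))
  expect_error(
    generate_trial(co$traits[[1]],
                   list(activity = "x", type = "nope",
                        subtrial_duration_s = 5, params = list()), 1),
    "unknown activity type")
})

test_that("SJRF is the documented deterministic function of the latents", {
  tr <- sample_traits(1, 0.3, seed = 3)
  tpl <- activity_templates(0.3)$propulsion_056
  rec <- generate_trial(tr, tpl, 1, noise_sd = 0, seed = 9)
  recomputed <- sjrf_from_latents(rec$latents, tr)
  expect_equal(unname(rec$sjrf$data), unname(recomputed), tolerance = 1e-12)
})

test_that("weight-relief holds are high-load relative to desk work", {
  tr <- sample_traits(1, 0, seed = 1)
  tpls <- activity_templates(0.5)
  wr <- generate_trial(tr, tpls$weight_relief, 1, noise_sd = 0, seed = 2)
  dw <- generate_trial(tr, tpls$desk_work, 1, noise_sd = 0, seed = 2)
  ft_wr <- compute_ftot(wr$sjrf$data)
  ft_dw <- compute_ftot(dw$sjrf$data)
  # compare the hold phase (central part) against desk work overall
  mid <- seq(floor(length(ft_wr) * 0.4), ceiling(length(ft_wr) * 0.6))
  expect_gt(mean(ft_wr[mid]), 3 * mean(ft_dw))
})

test_that("wheel gyro oscillates at the propulsion cadence", {
  tr <- sample_traits(1, 0, seed = 1)
  tr$cadence_hz <- 1.0
  tpl <- activity_templates(1)$propulsion_056 # full 15 s for resolution
  rec <- generate_trial(tr, tpl, 1, noise_sd = 0, seed = 2,
                        include_burst = FALSE)
  g <- rec$imu$wc_wheel$data[, "gyro_y"]
  # analyse the activity portion only
  idx <- rec$imu$wc_wheel$time > 2 & rec$imu$wc_wheel$time < 16
  x <- g[idx] - mean(g[idx])
  sp <- stats::spec.pgram(ts(x, frequency = 128), plot = FALSE, taper = 0)
  f_dom <- sp$freq[which.max(sp$spec)]
  df <- diff(sp$freq)[1]
  expect_lt(abs(f_dom - 1.0), df + 1e-9)
})

test_that("cohort counts, exclusions and determinism", {
  co <- smoke_cohort(n_participants = 2, n_exclusions = 3, seed = 11)
  expect_identical(nrow(co$manifest), 38L)
  expect_identical(sum(co$manifest$valid), 35L)
  expect_false(anyDuplicated(co$manifest$key) > 0)
  # one participant alone: all 19 subtrials valid with no exclusions
  co1 <- smoke_cohort(n_participants = 1, n_exclusions = 0, seed = 11)
  expect_identical(sum(co1$manifest$valid), 19L)
  # determinism: identical seeds give identical manifests and signals
  co_b <- generate_cohort(n_participants = 2, noise_sd = 1, seed = 11,
                          duration_scale = 0.2, n_exclusions = 3)
  expect_identical(co$manifest, co_b$manifest)
  expect_identical(co$recordings[[5]]$imu$thorax$data,
                   co_b$recordings[[5]]$imu$thorax$data)
  expect_error(generate_cohort(n_participants = 1, n_exclusions = 19,
                               duration_scale = 0.2), "smaller")
})

test_that("forced orphan leaves exactly one valid weight-relief subtrial", {
  co <- smoke_cohort(n_participants = 2, n_exclusions = 2, seed = 13,
                     force_orphan = TRUE)
  wr <- co$manifest[co$manifest$activity == "weight_relief", ]
  n_valid <- tapply(wr$valid, wr$participant_id, sum)
  expect_true(any(n_valid == 1))
})

test_that("cohort round-trips through the CSV/YAML layout", {
  co <- generate_cohort(n_participants = 1, noise_sd = 0.5, seed = 21,
                        duration_scale = 0.15, n_exclusions = 2)
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  back <- read_cohort(dir)
  expect_identical(back$manifest$key, co$manifest$key)
  expect_identical(back$manifest$valid, co$manifest$valid)
  key <- co$manifest$key[1]
  expect_equal(back$recordings[[key]]$imu$upper_arm$data,
               co$recordings[[key]]$imu$upper_arm$data, tolerance = 1e-12)
  expect_equal(back$recordings[[key]]$stream_offsets_s,
               co$recordings[[key]]$stream_offsets_s, tolerance = 1e-9)
  # byte-identical files on re-write with the same seed
  dir2 <- withr::local_tempdir()
  write_cohort(generate_cohort(n_participants = 1, noise_sd = 0.5, seed = 21,
                               duration_scale = 0.15, n_exclusions = 2), dir2)
  f <- paste0(key, "_imu_upper_arm.csv")
  expect_identical(readLines(file.path(dir, f)), readLines(file.path(dir2, f)))
})
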