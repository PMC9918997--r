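# Synthetic wheelchair-activity cohort: raw multi-rate IMU/EMG streams plus
# ground-truth shoulder-joint reaction force (SJRF) with a known nonlinear
# generative mapping, so the whole estimation pipeline can be exercised and
# tested without access to laboratory data.

IMU_FS <- 128    # Hz, inertial streams
EMG_FS <- 1024   # Hz, electromyography streams
SJRF_FS <- 100   # Hz, native rate of the ground-truth force series

IMU_STREAMS <- c("lower_arm", "upper_arm", "thorax", "wc_frame", "wc_wheel")
EMG_STREAMS <- c("biceps_long_head", "deltoid_medial")
IMU_CHANNELS <- c("acc_x", "acc_y", "acc_z", "gyro_x", "gyro_y", "gyro_z")

# lead-in before activity onset: fiducial burst on [0.6, 1.2] s of the
# recording clock, placed so it stays fully recorded and fully outside the
# aligned activity window for inter-stream clock offsets of up to +-0.5 s
TRIAL_LEAD_S <- 1.8
TRIAL_TAIL_S <- 0.5

# configured between-participant trait spreads at heterogeneity = 1
# (multiplied by the heterogeneity argument of sample_traits)
TRAIT_SD <- list(body_mass = 0.35, cadence = 0.5, emg_gain_log = 0.4,
                 kinematic_offset = 0.3)

#' Activity templates of the synthetic cohort
#'
#' The eight evaluation activities with their subtrial counts (two, three or
#' six subtrials per original activity, 19 in total per participant) and
#' per-subtrial durations. Treadmill propulsion appears as three separate
#' activities (slow, fast, incline), each contributing two subtrials of one
#' 30 s bout.
#'
#' @param duration_scale Multiplier on all subtrial durations; values below 1
#'   give shortened trials for fast experimentation.
#' @return Named list of templates, each with `activity`, `type`,
#'   `n_subtrials`, `subtrial_duration_s` and a `params` list.
#' @export
activity_templates <- function(duration_scale = 1) {
  stopifnot_scalar_num(duration_scale, "duration_scale", min = 1e-6)
  tpl <- function(activity, type, n, dur, params = list()) {
    list(activity = activity, type = type, n_subtrials = n,
         subtrial_duration_s = dur * duration_scale, params = params)
  }
  out <- list(
    tpl("propulsion_056",  "propulsion", 2L, 15,
        list(cadence_scale = 1.00, push_amp = 45, wheel_base = 35)),
    tpl("propulsion_110",  "propulsion", 2L, 15,
        list(cadence_scale = 1.25, push_amp = 55, wheel_base = 65)),
    tpl("propulsion_056_incline", "propulsion", 2L, 15,
        list(cadence_scale = 0.95, push_amp = 70, wheel_base = 35)),
    tpl("propulsion_restricted", "restricted", 3L, 10),
    tpl("ramp", "ramp", 2L, 6),
    tpl("weight_relief", "weight_relief", 2L, 10),
    tpl("material_handling", "material_handling", 3L, 8),
    tpl("desk_work", "desk_work", 3L, 10)
  )
  names(out) <- vapply(out, `[[`, "", "activity")
  out
}

#' Static-posture template for EMG normalization
#'
#' A quasi-static submaximal isometric hold (weight held in abduction /
#' elbow flexion) used to derive per-muscle EMG reference values.
#'
#' @param duration_s Hold duration in seconds.
#' @return A template usable with [generate_trial()].
#' @export
static_posture_template <- function(duration_s = 6) {
  list(activity = "static_posture", type = "static_posture", n_subtrials = 1L,
       subtrial_duration_s = duration_s, params = list())
}

#' Sample participant traits
#'
#' Draws the per-participant parameters that create inter-participant
#' heterogeneity: a force-magnitude multiplier (`body_mass_scale`, normal
#' around 1 with SD `0.35 * heterogeneity`), propulsion cadence
#' (`cadence_hz`, normal around 1.1 Hz with SD `0.5 * heterogeneity`,
#' clamped to (0.55, 1.9)), log-normal per-muscle EMG gains (log-SD
#' `0.4 * heterogeneity`) and additive per-axis IMU biases (SD
#' `0.3 * heterogeneity`). At `heterogeneity = 0` every participant gets the
#' identical baseline traits.
#'
#' @param participant_id Integer id.
#' @param heterogeneity Non-negative spread multiplier.
#' @param seed Cohort-level integer seed; traits are a pure function of
#'   `(participant_id, heterogeneity, seed)`.
#' @return A list of class `sjrf_traits`.
#' @export
sample_traits <- function(participant_id, heterogeneity = 0.3, seed = 1) {
  stopifnot_scalar_num(heterogeneity, "heterogeneity", min = 0)
  with_seed(child_seed(seed, 11, participant_id), {
    z <- stats::rnorm(7)
    traits <- list(
      participant_id = as.integer(participant_id),
      body_mass_scale = max(1 + heterogeneity * TRAIT_SD$body_mass * z[1], 0.3),
      cadence_hz = min(max(1.1 + heterogeneity * TRAIT_SD$cadence * z[2], 0.55),
                       1.9),
      emg_gain = stats::setNames(
        exp(heterogeneity * TRAIT_SD$emg_gain_log * z[3:4]), EMG_STREAMS),
      kinematic_offset = heterogeneity * TRAIT_SD$kinematic_offset * z[5:7],
      seed = as.integer(seed)
    )
    class(traits) <- "sjrf_traits"
    traits
  })
}

# Latent states over activity-relative time t (seconds since activity onset;
# clamped to [0, duration]). Returns smooth series: arm elevation theta (rad),
# hand-rim/push force (N), two muscle activations in [0, 1], and wheel
# rotation rate (deg/s). phase_seed randomizes only the desk-work phases.
latent_states <- function(template, subtrial, traits, t, phase_seed = 0L) {
  dur <- template$subtrial_duration_s
  tc <- pmin(pmax(t, 0), dur)
  p <- template$params
  two_pi <- 2 * pi
  type <- template$type
  if (type == "propulsion") {
    f <- traits$cadence_hz * p$cadence_scale
    ph <- two_pi * f * tc
    lat <- list(
      theta = 0.45 + 0.18 * sin(ph),
      push = p$push_amp * pmax(sin(ph), 0)^2,
      act_bic = 0.15 + 0.45 * pmax(sin(ph + 0.6), 0),
      act_del = 0.12 + 0.38 * pmax(sin(ph + 1.3), 0),
      wheel_rate = p$wheel_base + 40 * sin(ph)
    )
  } else if (type == "restricted") {
    f1 <- 0.45 * traits$cadence_hz / 1.1
    f2 <- 0.85
    lat <- list(
      theta = 0.5 + 0.14 * sin(two_pi * f1 * tc) +
        0.08 * sin(two_pi * f2 * tc + 1.1),
      push = 35 * pmax(sin(two_pi * f1 * tc), 0)^2 *
        (1 + 0.3 * sin(two_pi * 0.17 * tc)),
      act_bic = 0.2 + 0.3 * pmax(sin(two_pi * f1 * tc + 0.5), 0) +
        0.1 * pmax(sin(two_pi * f2 * tc), 0),
      act_del = 0.15 + 0.25 * pmax(sin(two_pi * f1 * tc + 1.0), 0),
      wheel_rate = 15 * sin(two_pi * f1 * tc) + 8 * sin(two_pi * 0.2 * tc)
    )
  } else if (type == "weight_relief") {
    w <- stats::plogis((tc - 0.2 * dur) / 0.25) *
      stats::plogis((0.8 * dur - tc) / 0.25)
    lat <- list(
      theta = 0.12 + 0.10 * w,
      push = 190 * w,
      act_bic = 0.10 + 0.80 * w,
      act_del = 0.08 + 0.65 * w,
      wheel_rate = rep(0, length(tc))
    )
  } else if (type == "material_handling") {
    centers <- dur * c(0.2, 0.5, 0.8)
    heights <- c(0.6, 0.85, 1.1) # three shelf levels
    wdt <- 0.08 * dur
    b <- rep(0, length(tc))
    for (k in 1:3) b <- b + heights[k] * exp(-0.5 * ((tc - centers[k]) / wdt)^2)
    lat <- list(
      theta = 0.3 + 0.85 * b,
      push = 18 * b,
      act_bic = 0.12 + 0.55 * b,
      act_del = 0.10 + 0.50 * b,
      wheel_rate = rep(0, length(tc))
    )
  } else if (type == "desk_work") {
    ph3 <- with_seed(child_seed(phase_seed, 31), stats::runif(3, 0, two_pi))
    lat <- list(
      theta = 0.25 + 0.03 * sin(two_pi * 0.25 * tc + ph3[1]) +
        0.02 * sin(two_pi * 0.45 * tc + ph3[2]),
      push = rep(0, length(tc)),
      act_bic = pmax(0.07 + 0.03 * sin(two_pi * 0.3 * tc + ph3[3]), 0),
      act_del = pmax(0.06 + 0.02 * sin(two_pi * 0.2 * tc + ph3[1]), 0),
      wheel_rate = rep(0, length(tc))
    )
  } else if (type == "ramp") {
    ascend <- subtrial == 1L
    w <- stats::plogis((tc - 0.15 * dur) / 0.3) *
      stats::plogis((0.85 * dur - tc) / 0.3)
    f <- traits$cadence_hz * 0.8
    s <- pmax(sin(two_pi * f * tc), 0)^2 * w
    lat <- list(
      theta = 0.4 + 0.15 * w * sin(two_pi * f * tc) +
        (if (ascend) 0.1 else -0.02) * w,
      push = (if (ascend) 85 else 65) * s, # descend: braking grip force
      act_bic = 0.15 + (if (ascend) 0.55 else 0.5) * s,
      act_del = 0.12 + 0.4 * s,
      wheel_rate = (if (ascend) 20 else 14) * w + 15 * sin(two_pi * f * tc) * w
    )
  } else if (type == "static_posture") {
    n <- length(tc)
    lat <- list(theta = rep(0.9, n), push = rep(0, n),
                act_bic = rep(0.45, n), act_del = rep(0.5, n),
                wheel_rate = rep(0, n))
  } else {
    stop("unknown activity type: ", type, call. = FALSE)
  }
  lat
}

#' Ground-truth SJRF from latent states
#'
#' The documented deterministic nonlinear mapping from latent states to the
#' three SJRF components. It deliberately contains non-affine terms — products
#' of muscle activation and arm elevation, a rectified push-force term, and
#' trigonometric redistribution over the axes — so that a linear readout of
#' the sensor channels is misspecified. The rectification threshold (35 N)
#' lies inside the push-force range of cyclic propulsion, so the kink is
#' crossed within every propulsion cycle. Muscle activations act on the
#' joint force through first-order activation dynamics (exponential lag,
#' time constant `tau_act` = 0.45 s), mirroring the combined electromechanical delay and force-development dynamics
#' between EMG and force: the force at time t therefore depends on the
#' recent history of the emitted EMG, not only its instantaneous value,
#' which is what gives a recurrent model its edge over a per-timestep
#' network. With `a* = lag(a)`:
#' \deqn{L = m (95\,a^*_{del}\theta + 70\,a^*_{bic}\theta)
#'       + m (0.9 \max(P-35,0) + 0.25 P) + 12}
#' with `m = body_mass_scale`, then `Fx = 0.35 L cos(theta)`,
#' `Fy = L (0.55 + 0.25 sin(theta))`, `Fz = 0.45 L - 20 a*_bic`.
#'
#' @param lat Latent-state list from the generator (uniformly sampled).
#' @param traits Participant traits.
#' @param dt Sampling interval of the latent series in seconds (the
#'   activation-dynamics filter is discretized at this step).
#' @param tau_act Activation-dynamics time constant in seconds.
#' @return N x 3 matrix with columns `Fx`, `Fy`, `Fz` (N).
#' @export
sjrf_from_latents <- function(lat, traits, dt = 1 / SJRF_FS, tau_act = 0.45) {
  m <- traits$body_mass_scale
  lag1 <- function(a) {
    alpha <- dt / (tau_act + dt)
    as.numeric(stats::filter(alpha * a, 1 - alpha, method = "recursive",
                             init = a[1]))
  }
  a_del <- lag1(lat$act_del)
  a_bic <- lag1(lat$act_bic)
  L <- m * (95 * a_del * lat$theta + 70 * a_bic * lat$theta) +
    m * (0.9 * pmax(lat$push - 35, 0) + 0.25 * lat$push) + 12
  cbind(Fx = 0.35 * L * cos(lat$theta),
        Fy = L * (0.55 + 0.25 * sin(lat$theta)),
        Fz = 0.45 * L - 20 * a_bic)
}

# triphasic fiducial burst on [0.6, 1.2] s of the recording clock; gives the
# cross-correlation synchronization a sharp common feature in every stream
fiducial_burst <- function(t) {
  u <- (t - 0.6) / 0.6
  b <- ifelse(u > 0 & u < 1, sin(3 * pi * u) * sin(pi * u), 0)
  b
}

# per-stream mixing of latent features into the six IMU channels
# feature order: sin(theta), cos(theta), dtheta [rad/s], push [N],
# wheel_rate [deg/s], intercept
imu_mixing <- function(stream) {
  g <- 9.81
  r <- 180 / pi
  M <- switch(stream,
    lower_arm = rbind(
      c(1.00 * g, 0, 0, 0.02, 0, 0),
      c(0, 0.95 * g, 0, 0, 0, 0),
      c(0.30 * g, 0, 0.40, 0, 0, 0),
      c(0, 0, 1.20 * r, 0, 0, 0),
      c(0, 0, 0.50 * r, 0, 0, 0),
      c(0, 0, 0.20 * r, 0, 0, 0)),
    upper_arm = rbind(
      c(1.00 * g, 0, 0, 0, 0, 0),
      c(0, 1.00 * g, 0, 0, 0, 0),
      c(0.25 * g, 0, 0.30, 0, 0, 0),
      c(0, 0, 1.00 * r, 0, 0, 0),
      c(0, 0, 0.40 * r, 0, 0, 0),
      c(0, 0, 0.15 * r, 0, 0, 0)),
    thorax = rbind(
      c(0.20 * g, 0, 0, 0, 0, 0),
      c(0, 0.95 * g, 0, 0, 0, 0),
      c(0.10 * g, 0, 0.10, 0, 0, 0),
      c(0, 0, 0.15 * r, 0, 0, 0),
      c(0, 0, 0.10 * r, 0, 0, 0),
      c(0, 0, 0.05 * r, 0, 0, 0)),
    wc_frame = rbind(
      c(0, 0, 0, 0.05, 0, 0),
      c(0, 0, 0, 0, 0, g),
      c(0, 0, 0, 0.02, 0, 0),
      c(0, 0, 0, 0, 0.05, 0),
      c(0, 0, 0, 0, 0.03, 0),
      c(0, 0, 0, 0, 0.02, 0)),
    wc_wheel = rbind(
      c(0, 0, 0, 0, 0.05, 0),
      c(0, 0, 0, 0, 0, g),
      c(0, 0, 0, 0.03, 0, 0),
      c(0, 0, 0, 0, 0.10, 0),
      c(0, 0, 0, 0, 1.00, 0),
      c(0, 0, 0, 0, 0.10, 0)),
    stop("unknown IMU stream: ", stream, call. = FALSE)
  )
  rownames(M) <- IMU_CHANNELS
  M
}

#' Generate one synthetic subtrial recording
#'
#' Produces the raw multi-rate streams of a single subtrial: five 6-channel
#' IMU streams at 128 Hz, two EMG channels at 1024 Hz (amplitude-modulated
#' broadband carrier), and the ground-truth SJRF at its native 100 Hz. Every
#' stream except the upper-arm IMU (the synchronization reference, which
#' defines the trial clock, as does the SJRF series) carries a hidden clock
#' offset drawn uniformly from `[-max_offset_s, max_offset_s]`; the injected
#' offsets are retained in the returned object for use as a test oracle. A
#' high-amplitude triphasic fiducial burst is superimposed on all sensor
#' streams at the start of the recording.
#'
#' @param traits Participant traits from [sample_traits()].
#' @param template An activity template.
#' @param subtrial Subtrial index within the activity.
#' @param noise_sd Non-negative multiplier on the per-channel measurement
#'   noise scales (0.3 m/s^2 accelerometer, 4 deg/s gyroscope, 0.03 a.u. EMG).
#' @param seed Integer seed; identical arguments give identical recordings.
#' @param max_offset_s Half-width of the hidden inter-stream offset range (s).
#' @param include_burst Superimpose the fiducial burst (default TRUE).
#' @return An object of class `sjrf_recording`.
#' @export
generate_trial <- function(traits, template, subtrial = 1L, noise_sd = 1,
                           seed = 1, max_offset_s = 0.5,
                           include_burst = TRUE) {
  stopifnot_scalar_num(noise_sd, "noise_sd", min = 0)
  dur <- template$subtrial_duration_s
  total <- TRIAL_LEAD_S + dur + TRIAL_TAIL_S
  tseed <- child_seed(seed, traits$participant_id,
                      sum(utf8ToInt(template$activity)), subtrial)

  with_seed(tseed, {
    offs <- stats::setNames(stats::runif(7, -max_offset_s, max_offset_s),
                            c(IMU_STREAMS, EMG_STREAMS))
    offs["upper_arm"] <- 0

    eval_latents <- function(t_nominal, offset) {
      latent_states(template, subtrial, traits,
                    t_nominal - offset - TRIAL_LEAD_S, phase_seed = tseed)
    }

    imu <- list()
    for (s in IMU_STREAMS) {
      tt <- seq(0, total, by = 1 / IMU_FS)
      lat <- eval_latents(tt, offs[[s]])
      dtheta <- c(0, diff(lat$theta)) * IMU_FS
      feat <- cbind(sin(lat$theta), cos(lat$theta), dtheta, lat$push,
                    lat$wheel_rate, 1)
      X <- feat %*% t(imu_mixing(s))
      if (s %in% c("lower_arm", "upper_arm", "thorax")) {
        X[, 1:3] <- sweep(X[, 1:3, drop = FALSE], 2, traits$kinematic_offset,
                          "+")
      }
      if (include_burst) {
        b <- fiducial_burst(tt - offs[[s]])
        X[, 1:3] <- X[, 1:3] + 8 * b
        X[, 4:6] <- X[, 4:6] + 120 * b
      }
      if (noise_sd > 0) {
        X[, 1:3] <- X[, 1:3] + noise_sd * 0.3 *
          matrix(stats::rnorm(3 * length(tt)), ncol = 3)
        X[, 4:6] <- X[, 4:6] + noise_sd * 4 *
          matrix(stats::rnorm(3 * length(tt)), ncol = 3)
      }
      colnames(X) <- IMU_CHANNELS
      imu[[s]] <- list(fs = IMU_FS, time = tt, data = X)
    }

    emg <- list()
    for (m in EMG_STREAMS) {
      tt <- seq(0, total, by = 1 / EMG_FS)
      lat <- eval_latents(tt, offs[[m]])
      act <- if (m == "biceps_long_head") lat$act_bic else lat$act_del
      carrier <- stats::rnorm(length(tt))
      x <- act * traits$emg_gain[[m]] * carrier
      if (include_burst) {
        x <- x + 3 * traits$emg_gain[[m]] * fiducial_burst(tt - offs[[m]])
      }
      if (noise_sd > 0) x <- x + noise_sd * 0.03 * stats::rnorm(length(tt))
      emg[[m]] <- list(fs = EMG_FS, time = tt,
                       data = matrix(x, ncol = 1, dimnames = list(NULL, "emg")))
    }

    tt <- seq(0, total, by = 1 / SJRF_FS)
    lat <- eval_latents(tt, 0)
    rec <- list(
      participant_id = traits$participant_id,
      activity = template$activity,
      subtrial = as.integer(subtrial),
      imu = imu, emg = emg,
      sjrf = list(fs = SJRF_FS, time = tt, data = sjrf_from_latents(lat, traits)),
      stream_offsets_s = offs,
      latents = lat,
      traits = traits,
      duration_s = dur,
      seed = tseed
    )
    class(rec) <- "sjrf_recording"
    rec
  })
}

#' Generate a synthetic wheelchair-activity cohort
#'
#' Builds the full cohort: `n_participants` participants, each performing the
#' eight activities split into 19 subtrials, plus one static-posture
#' recording per participant for EMG normalization. `n_exclusions` subtrials
#' are flagged invalid (pseudo-randomly, seeded) but kept in the manifest,
#' mirroring processing failures of ground-truth extraction. With the default
#' 10 participants and 7 exclusions the cohort contains 183 valid subtrials.
#'
#' @param n_participants Number of participants (default 10).
#' @param heterogeneity Trait spread multiplier, see [sample_traits()].
#' @param noise_sd Measurement-noise multiplier, see [generate_trial()].
#' @param n_exclusions Number of subtrials to flag invalid (default 7).
#' @param seed Integer master seed.
#' @param duration_scale Multiplier on subtrial durations.
#' @param max_offset_s Hidden inter-stream offset half-width (s).
#' @param force_orphan If TRUE, one participant (id 5 when present, else the
#'   first) has exactly one of their two weight-relief subtrials excluded, so
#'   the remaining one has no same-activity training data under
#'   leave-one-trial-out validation.
#' @param out_dir Optional directory; when given, the cohort is also written
#'   as CSV streams + YAML sidecars + a manifest via [write_cohort()].
#' @return An object of class `sjrf_cohort`: `manifest` (data frame with
#'   `participant_id`, `activity`, `subtrial`, `key`, `valid`), `recordings`
#'   (named list), `static` (per-participant static recordings), `traits`.
#' @export
generate_cohort <- function(n_participants = 10, heterogeneity = 0.3,
                            noise_sd = 1, n_exclusions = 7, seed = 1,
                            duration_scale = 1, max_offset_s = 0.5,
                            force_orphan = FALSE, out_dir = NULL) {
  stopifnot(n_participants >= 1)
  templates <- activity_templates(duration_scale)
  stopifnot(sum(vapply(templates, `[[`, 0L, "n_subtrials")) == 19L)

  manifest <- do.call(rbind, lapply(seq_len(n_participants), function(p) {
    do.call(rbind, lapply(templates, function(tp) {
      data.frame(participant_id = p, activity = tp$activity,
                 subtrial = seq_len(tp$n_subtrials),
                 stringsAsFactors = FALSE)
    }))
  }))
  rownames(manifest) <- NULL
  manifest$key <- mapply(subtrial_key, manifest$participant_id,
                         manifest$activity, manifest$subtrial)
  if (n_exclusions >= nrow(manifest)) {
    stop("n_exclusions must be smaller than the total number of subtrials")
  }
  manifest$valid <- TRUE

  excl <- integer(0)
  if (n_exclusions > 0) {
    excl <- with_seed(child_seed(seed, 97), {
      if (force_orphan) {
        p_orph <- if (n_participants >= 5) 5L else 1L
        wr <- which(manifest$participant_id == p_orph &
                      manifest$activity == "weight_relief")
        orphaned <- sample(wr, 1)
        pool <- setdiff(seq_len(nrow(manifest)), wr)
        c(orphaned, sample(pool, n_exclusions - 1))
      } else {
        sample(seq_len(nrow(manifest)), n_exclusions)
      }
    })
    manifest$valid[excl] <- FALSE
  }

  traits <- lapply(seq_len(n_participants), sample_traits,
                   heterogeneity = heterogeneity, seed = seed)
  recordings <- vector("list", nrow(manifest))
  names(recordings) <- manifest$key
  for (i in seq_len(nrow(manifest))) {
    p <- manifest$participant_id[i]
    tp <- templates[[manifest$activity[i]]]
    recordings[[i]] <- generate_trial(traits[[p]], tp, manifest$subtrial[i],
                                      noise_sd = noise_sd, seed = seed,
                                      max_offset_s = max_offset_s)
  }
  static <- lapply(seq_len(n_participants), function(p) {
    generate_trial(traits[[p]], static_posture_template(6 * max(duration_scale, 0.5)),
                   1L, noise_sd = noise_sd, seed = child_seed(seed, 41, p),
                   max_offset_s = max_offset_s)
  })

  cohort <- list(manifest = manifest, recordings = recordings,
                 static = static, traits = traits,
                 params = list(n_participants = n_participants,
                               heterogeneity = heterogeneity,
                               noise_sd = noise_sd,
                               n_exclusions = n_exclusions, seed = seed,
                               duration_scale = duration_scale,
                               max_offset_s = max_offset_s,
                               force_orphan = force_orphan))
  class(cohort) <- "sjrf_cohort"
  if (!is.null(out_dir)) write_cohort(cohort, out_dir)
  cohort
}

#' @export
print.sjrf_cohort <- function(x, ...) {
  cat("Synthetic wheelchair-activity cohort\n")
  cat(sprintf("  participants: %d\n", x$params$n_participants))
  cat(sprintf("  subtrials:    %d (%d valid, %d excluded)\n",
              nrow(x$manifest), sum(x$manifest$valid),
              sum(!x$manifest$valid)))
  cat(sprintf("  heterogeneity %.2f, noise %.2f, seed %d\n",
              x$params$heterogeneity, x$params$noise_sd, x$params$seed))
  invisible(x)
}

# ---- file round-trip ------------------------------------------------------

#' Write a cohort to disk
#'
#' One CSV per stream per subtrial (first column time in seconds, then named
#' channels), one YAML sidecar per subtrial with sampling rates, the traits
#' hash, and the hidden stream offsets (oracle metadata, not read by the
#' pipeline), and a cohort-level `manifest.csv`.
#'
#' @param cohort An `sjrf_cohort`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_recording <- function(rec, prefix) {
    for (s in names(rec$imu)) {
      df <- data.frame(time_s = rec$imu[[s]]$time, rec$imu[[s]]$data,
                       check.names = FALSE)
      utils::write.csv(df, file.path(dir, paste0(prefix, "_imu_", s, ".csv")),
                       row.names = FALSE)
    }
    for (s in names(rec$emg)) {
      df <- data.frame(time_s = rec$emg[[s]]$time, rec$emg[[s]]$data,
                       check.names = FALSE)
      utils::write.csv(df, file.path(dir, paste0(prefix, "_emg_", s, ".csv")),
                       row.names = FALSE)
    }
    df <- data.frame(time_s = rec$sjrf$time, rec$sjrf$data,
                     check.names = FALSE)
    utils::write.csv(df, file.path(dir, paste0(prefix, "_sjrf.csv")),
                     row.names = FALSE)
    meta <- list(participant_id = rec$participant_id, activity = rec$activity,
                 subtrial = rec$subtrial, duration_s = rec$duration_s,
                 fs = list(imu = IMU_FS, emg = EMG_FS, sjrf = SJRF_FS),
                 stream_offsets_s = as.list(rec$stream_offsets_s),
                 traits_hash = sum(unlist(rec$traits[
                   c("body_mass_scale", "cadence_hz")])),
                 seed = rec$seed)
    yaml::write_yaml(meta, file.path(dir, paste0(prefix, "_meta.yaml")),
                     precision = 12)
  }
  for (key in names(cohort$recordings)) {
    write_recording(cohort$recordings[[key]], key)
  }
  for (p in seq_along(cohort$static)) {
    write_recording(cohort$static[[p]], sprintf("p%02d_static", p))
  }
  utils::write.csv(cohort$manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' Read a cohort written by [write_cohort()]
#'
#' Reconstructs the manifest and all recordings from the CSV/YAML layout.
#' The hidden stream offsets from the sidecars are attached for oracle use;
#' latent states are not serialized.
#'
#' @param dir Cohort directory.
#' @return An `sjrf_cohort` (without `traits`/`latents`).
#' @export
read_cohort <- function(dir) {
  man_path <- file.path(dir, "manifest.csv")
  if (!file.exists(man_path)) stop("no manifest.csv under ", dir)
  manifest <- utils::read.csv(man_path, stringsAsFactors = FALSE)
  read_recording <- function(prefix) {
    meta <- yaml::read_yaml(file.path(dir, paste0(prefix, "_meta.yaml")))
    rd <- function(path, fs) {
      df <- utils::read.csv(path, check.names = FALSE)
      list(fs = fs, time = df[[1]],
           data = as.matrix(df[, -1, drop = FALSE]))
    }
    imu <- lapply(stats::setNames(IMU_STREAMS, IMU_STREAMS), function(s) {
      rd(file.path(dir, paste0(prefix, "_imu_", s, ".csv")), meta$fs$imu)
    })
    emg <- lapply(stats::setNames(EMG_STREAMS, EMG_STREAMS), function(s) {
      rd(file.path(dir, paste0(prefix, "_emg_", s, ".csv")), meta$fs$emg)
    })
    rec <- list(participant_id = meta$participant_id,
                activity = meta$activity, subtrial = meta$subtrial,
                imu = imu, emg = emg,
                sjrf = rd(file.path(dir, paste0(prefix, "_sjrf.csv")),
                          meta$fs$sjrf),
                stream_offsets_s = unlist(meta$stream_offsets_s),
                duration_s = meta$duration_s, seed = meta$seed)
    class(rec) <- "sjrf_recording"
    rec
  }
  recordings <- lapply(stats::setNames(manifest$key, manifest$key),
                       read_recording)
  statics <- sort(unique(manifest$participant_id))
  static <- lapply(statics, function(p) read_recording(sprintf("p%02d_static", p)))
  cohort <- list(manifest = manifest, recordings = recordings, static = static,
                 params = list(n_participants = length(statics)))
  class(cohort) <- "sjrf_cohort"
  cohort
}
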