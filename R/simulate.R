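# Synthetic gait cohort generator.
#
# A cohort is n_subjects x 3 conditions x n_trials straight 5 m walks. Each
# trial yields (i) a 50 Hz IMU record of bilateral thigh/shank sagittal
# angles plus shank angular velocities, (ii) a walkway footfall record
# (heel positions and contact/off times), and (iii) ground-truth heel-strike
# and toe-off times. Trial-level gait descriptors ("drivers": cycle time,
# swing times, segment ranges of motion, step lengths, step times, base of
# support) are drawn around the condition-effect targets with a configurable
# between-subject / within-subject variance split; the remaining parameters
# (stance times, phases, cadence, stride length, support times, symmetry
# ratios) emerge from the waveform and foot-placement model.

IMU_SAMPLE_RATE <- 50
N_CORE_CYCLES <- 5L       # complete gait cycles per leg per trial
EDGE_GUARD_S <- 0.25      # events closer than this to the record edge are
                          # treated as lacking context (both in ground truth
                          # and in the detector)

# driver keys for subject-level baseline offsets
.driver_keys <- c(
  "imu_cycle_time", "imu_swing_L", "imu_swing_R",
  "imu_shank_L", "imu_shank_R", "imu_thigh_L", "imu_thigh_R",
  "imu_knee_L", "imu_knee_R", "imu_offset",
  "wk_step_len_L", "wk_step_len_R", "wk_bos",
  "wk_step_time_L", "wk_step_time_R", "wk_swing_L", "wk_swing_R")

# right-foot step-time fraction of the stride (left-right phase offset)
.offset_frac <- c(normal = 0.50, knee = 0.53, ankle = 0.53)

# left/right pairs among the driver keys; a subject's (and a trial's) left
# and right values of the same parameter are correlated — individual gait
# style is largely bilateral — while different parameter families stay
# independent
.driver_pairs <- list(
  c("imu_swing_L", "imu_swing_R"), c("imu_thigh_L", "imu_thigh_R"),
  c("wk_step_len_L", "wk_step_len_R"), c("wk_step_time_L", "wk_step_time_R"),
  c("wk_swing_L", "wk_swing_R"))
# the four angular drivers (shank/knee x L/R) additionally share a per-leg
# restriction factor: same-parameter-across-legs and same-leg-across-
# parameters correlations both equal rho, the diagonal correlation rho^2
.angular_keys <- c("imu_shank_L", "imu_shank_R", "imu_knee_L", "imu_knee_R")
RHO_SUBJECT <- 0.7   # correlation of subject-level offsets
RHO_TRIAL <- 0.5     # correlation of trial-level deviations

# standard-normal draws for all driver keys with the correlation structure
.correlated_z <- function(rho) {
  z <- stats::setNames(stats::rnorm(length(.driver_keys)), .driver_keys)
  for (p in .driver_pairs) {
    zc <- stats::rnorm(1)
    z[p] <- sqrt(rho) * zc + sqrt(1 - rho) * z[p]
  }
  # factor model for the angular block: global + parameter + side factors
  a <- rho; b <- sqrt(rho - rho^2)
  zg <- stats::rnorm(1)
  zpar <- stats::setNames(stats::rnorm(2), c("shank", "knee"))
  zside <- stats::setNames(stats::rnorm(2), c("L", "R"))
  for (key in .angular_keys) {
    par <- if (grepl("shank", key)) "shank" else "knee"
    side <- substring(key, nchar(key))
    z[key] <- a * zg + b * zpar[[par]] + b * zside[[side]] +
      (1 - rho) * z[[key]]
  }
  z
}

#' Simulation configuration
#'
#' @param n_subjects Number of subjects (>= 2).
#' @param n_trials Trials per subject per condition (>= 1).
#' @param seed Root seed; every random draw in the cohort derives from it.
#' @param variance_split Fraction of each parameter's total variance placed at
#'   the between-subject level (the rest is trial-to-trial).
#' @param conditions Walking conditions to simulate.
#' @param effects_overrides Optional data.frame of per-cell overrides, see
#'   [condition_effects()]; may include a `condition` column to target a
#'   single condition.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_subjects = 10L, n_trials = 10L, seed = 1L,
                       variance_split = 0.6,
                       conditions = c("normal", "knee", "ankle"),
                       effects_overrides = NULL) {
  abort_if(!is_count(n_subjects) || n_subjects < 2, "invalid config: n_subjects must be an integer >= 2")
  abort_if(!is_count(n_trials), "invalid config: n_trials must be an integer >= 1")
  abort_if(!is.numeric(seed) || length(seed) != 1L || !is.finite(seed),
           "invalid config: seed must be a single number")
  abort_if(!is.numeric(variance_split) || length(variance_split) != 1L ||
             variance_split < 0 || variance_split > 1,
           "invalid config: variance_split must be in [0, 1]")
  abort_if(!all(conditions %in% c("normal", "knee", "ankle")) ||
             length(conditions) < 1, "invalid config: conditions")
  structure(list(n_subjects = as.integer(n_subjects),
                 n_trials = as.integer(n_trials), seed = seed,
                 variance_split = variance_split,
                 conditions = conditions,
                 effects_overrides = effects_overrides),
            class = "sim_config")
}

#' Simulate a subject profile
#'
#' Demographics are drawn uniformly within the study cohort's observed ranges
#' (age 27-59 years, height 165-188 cm, weight 65-100 kg). Baseline offsets
#' are standard-normal subject-level deviations, one per driver parameter,
#' later scaled by each condition's between-subject SD — the same offsets
#' apply across conditions, which is what gives the repeated-measures
#' structure its within-subject consistency.
#'
#' @param seed Root seed.
#' @param index Subject index (1-based).
#' @return A `subject_profile` list.
#' @export
simulate_subject <- function(seed, index) {
  abort_if(!is_count(index), "index must be a positive integer")
  with_stream(seed, "subject", index, expr = {
    profile <- list(
      subject_id = sprintf("S%02d", index),
      age = round(stats::runif(1, 27, 59), 1),
      height = round(stats::runif(1, 165, 188), 1),
      weight = round(stats::runif(1, 65, 100), 1),
      baseline_offsets = .correlated_z(RHO_SUBJECT))
    structure(profile, class = "subject_profile")
  })
}

# Draw one trial-level driver value around its condition target.
.draw_driver <- function(target, z_subject, eps_trial, split) {
  target[["mean"]] +
    z_subject * target[["sd"]] * sqrt(split) +
    eps_trial * target[["sd"]] * sqrt(1 - split)
}

# Draw the full set of trial-level drivers; returns NULL when a draw violates
# the physical constraints (caller redraws).
.draw_trial_drivers <- function(profile, effects, split) {
  z <- profile$baseline_offsets
  eps <- .correlated_z(RHO_TRIAL)
  dd <- function(key, system, parameter, side = "")
    .draw_driver(effect_cell(effects, system, parameter, side),
                 z[[key]], eps[[key]], split)
  d <- list(
    cycle_time = dd("imu_cycle_time", "imu", "cycle_time", "L"),
    swing_L = dd("imu_swing_L", "imu", "swing_time", "L"),
    swing_R = dd("imu_swing_R", "imu", "swing_time", "R"),
    shank_L = dd("imu_shank_L", "imu", "shank_sagittal_angle", "L"),
    shank_R = dd("imu_shank_R", "imu", "shank_sagittal_angle", "R"),
    knee_L = dd("imu_knee_L", "imu", "knee_sagittal_angle", "L"),
    knee_R = dd("imu_knee_R", "imu", "knee_sagittal_angle", "R"),
    offset_frac = .offset_frac[[effects$condition]] +
      z[["imu_offset"]] * 0.01 + stats::rnorm(1) * 0.015,
    step_len_L = dd("wk_step_len_L", "walkway", "step_length", "L"),
    step_len_R = dd("wk_step_len_R", "walkway", "step_length", "R"),
    bos = .draw_driver(
      list(mean = mean(c(effect_cell(effects, "walkway", "base_of_support", "L")[["mean"]],
                         effect_cell(effects, "walkway", "base_of_support", "R")[["mean"]])),
           sd = effect_cell(effects, "walkway", "base_of_support", "L")[["sd"]]),
      z[["wk_bos"]], eps[["wk_bos"]], split),
    step_time_L = dd("wk_step_time_L", "walkway", "step_time", "L"),
    step_time_R = dd("wk_step_time_R", "walkway", "step_time", "R"),
    wk_swing_L = dd("wk_swing_L", "walkway", "swing_time", "L"),
    wk_swing_R = dd("wk_swing_R", "walkway", "swing_time", "R"))

  # The thigh ROM is geometrically floored by shank ROM - knee ROM (the thigh
  # trace is the shank trace plus knee flexion), so it is generated as that
  # difference plus a positive lognormal gap whose mean reproduces the
  # condition target: E[thigh] = E[shank] - E[knee] + g0 = target mean.
  for (side in c("L", "R")) {
    tgt <- effect_cell(effects, "imu", "thigh_sagittal_angle", side)
    sh <- effect_cell(effects, "imu", "shank_sagittal_angle", side)
    kn <- effect_cell(effects, "imu", "knee_sagittal_angle", side)
    g0 <- max(tgt[["mean"]] - sh[["mean"]] + kn[["mean"]], 0.5)
    sd_g <- min(g0 / 2, 3)
    key <- paste0("imu_thigh_", side)
    zt <- sqrt(split) * z[[key]] + sqrt(1 - split) * eps[[key]]
    tau <- sqrt(log(1 + (sd_g / g0)^2))
    gap <- g0 * exp(tau * zt - tau^2 / 2)
    d[[paste0("thigh_", side)]] <-
      d[[paste0("shank_", side)]] - d[[paste0("knee_", side)]] + gap
  }

  # swing and stance both bound the trough spacing seen by the event
  # detector (20 samples at 50 Hz = 0.40 s); keep a margin above it
  ok <- d$cycle_time > 0.5 &&
    d$swing_L > 0.43 && d$swing_R > 0.43 &&
    (d$cycle_time - d$swing_L) > 0.43 && (d$cycle_time - d$swing_R) > 0.43 &&
    d$swing_L < 0.60 * d$cycle_time && d$swing_R < 0.60 * d$cycle_time &&
    (d$cycle_time - d$swing_L) < 0.75 * d$cycle_time &&
    (d$cycle_time - d$swing_R) < 0.75 * d$cycle_time &&
    d$shank_L > 5 && d$shank_R > 5 && d$knee_L > 2 && d$knee_R > 2 &&
    d$thigh_L > 5 && d$thigh_R > 5 &&
    d$offset_frac > 0.35 && d$offset_frac < 0.65 &&
    d$step_len_L > 15 && d$step_len_R > 15 && d$bos > 1 &&
    d$step_time_L > 0.25 && d$step_time_R > 0.25 &&
    d$wk_swing_L > 0.15 && d$wk_swing_R > 0.15 &&
    d$wk_swing_L < 0.9 * (d$step_time_L + d$step_time_R) &&
    d$wk_swing_R < 0.9 * (d$step_time_L + d$step_time_R)
  if (!ok) return(NULL)
  d
}

# Build the IMU record plus ground truth for one trial from drawn drivers.
.build_imu <- function(d, fs = IMU_SAMPLE_RATE, n_cycles = N_CORE_CYCLES,
                       guard = EDGE_GUARD_S) {
  tmpl <- gait_templates()
  K <- n_cycles
  n_ext <- K + 4L                       # lead-in and lead-out cycles
  core <- 3:(K + 2L)                    # indices of the core cycles
  Tj <- d$cycle_time * (1 + stats::rnorm(n_ext) * 0.015)
  hs_L <- c(0, cumsum(Tj))
  off <- pmin(pmax(d$offset_frac + stats::rnorm(n_ext + 1L) * 0.01, 0.3), 0.7)
  hs_R <- hs_L + off * c(Tj, Tj[n_ext])
  TjR <- diff(hs_R)

  swing <- function(mu, n) pmax(mu * (1 + stats::rnorm(n) * 0.015), 0.41)
  sw_L <- pmin(swing(d$swing_L, n_ext), Tj - 0.41)
  sw_R <- pmin(swing(d$swing_R, n_ext), TjR - 0.41)
  cfrac_L <- (Tj - sw_L) / Tj
  cfrac_R <- (TjR - sw_R) / TjR

  amp <- function(mu, n) pmax(mu * (1 + stats::rnorm(n) * 0.02), 1)
  As_L <- amp(d$shank_L, n_ext); As_R <- amp(d$shank_R, n_ext)
  Ak_L <- amp(d$knee_L, n_ext);  Ak_R <- amp(d$knee_R, n_ext)
  shift_L <- solve_knee_shift(d$shank_L, d$knee_L, d$thigh_L, tmpl)
  shift_R <- solve_knee_shift(d$shank_R, d$knee_R, d$thigh_R, tmpl)

  Tm <- mean(Tj)
  gs <- hs_L[3] - 0.60 * Tm
  ge <- hs_L[K + 3L] + 0.85 * Tm
  nsamp <- floor((ge - gs) * fs) + 1L
  tt <- gs + (seq_len(nsamp) - 1L) / fs

  # render, then correct the knee-bump shift once against the *realised*
  # per-cycle thigh ROM (sampling, warping and amplitude jitter perturb it
  # slightly relative to the continuous-phase solution)
  rom_core <- function(sig, hs) {
    mean(vapply(core, function(j) {
      w <- tt >= hs[j] & tt <= hs[j + 1L]
      diff(range(sig[w]))
    }, 0))
  }
  render_corrected <- function(hs, cf, As, Ak, shift0, a_s, a_k, a_t) {
    out <- render_leg(tt, hs, cf, As, Ak, shift0, tmpl)
    err <- rom_core(out$thigh, hs) - a_t
    shift1 <- solve_knee_shift(a_s, a_k, max(a_t - err, 5), tmpl)
    render_leg(tt, hs, cf, As, Ak, shift1, tmpl)
  }
  left <- render_corrected(hs_L, cfrac_L, As_L, Ak_L, shift_L,
                           d$shank_L, d$knee_L, d$thigh_L)
  right <- render_corrected(hs_R, cfrac_R, As_R, Ak_R, shift_R,
                            d$shank_R, d$knee_R, d$thigh_R)

  smooth_noise <- function(n, sd = 0.15, w = 5L) {
    x <- stats::rnorm(n + w, sd = sd)
    as.numeric(stats::filter(x, rep(1 / w, w), sides = 2L))[seq_len(n) + 2L]
  }
  ang <- list(shank_L = left$shank + smooth_noise(nsamp),
              thigh_L = left$thigh + smooth_noise(nsamp),
              shank_R = right$shank + smooth_noise(nsamp),
              thigh_R = right$thigh + smooth_noise(nsamp))
  angvel <- function(a) {
    v <- c(a[2] - a[1], (a[-(1:2)] - a[-((nsamp - 1):nsamp)]) / 2,
           a[nsamp] - a[nsamp - 1]) * fs
    v
  }

  # ground truth: core events whose labelling context (the mid-swing peak)
  # and the event itself lie safely inside the record
  truth_leg <- function(hs, cf, leg) {
    ncyc <- length(hs) - 1L
    st <- cf * diff(hs)
    to_t <- hs[seq_len(ncyc)] + st
    pk_t <- hs[seq_len(ncyc)] + st + 0.55 * (diff(hs) - st)
    in_guard <- function(t) t >= gs + guard & t <= ge - guard
    pk_ok <- pk_t >= gs + 0.1 & pk_t <= ge - 0.1
    hs_keep <- which(in_guard(hs[-1]) & pk_ok)          # HS_{j+1} needs peak j
    to_keep <- which(in_guard(to_t) & pk_ok)            # TO_j needs peak j
    ev <- rbind(
      data.frame(leg = leg, type = "HS", time = hs[hs_keep + 1L]),
      data.frame(leg = leg, type = "TO", time = to_t[to_keep]))
    ev[order(ev$time), , drop = FALSE]
  }
  truth <- rbind(truth_leg(hs_L, cfrac_L, "L"), truth_leg(hs_R, cfrac_R, "R"))
  truth$time <- truth$time - gs
  rownames(truth) <- NULL

  data <- data.frame(
    time = tt - gs,
    angle_thigh_L = ang$thigh_L, angle_thigh_R = ang$thigh_R,
    angle_shank_L = ang$shank_L, angle_shank_R = ang$shank_R,
    angvel_shank_L = angvel(ang$shank_L), angvel_shank_R = angvel(ang$shank_R))
  list(data = data, truth = truth)
}

# Build the walkway footfall record for one trial from drawn drivers.
.build_walkway <- function(d, path_cm = 500, min_contacts_per_side = 4L,
                           max_contacts = 16L) {
  stride_time <- d$step_time_L + d$step_time_R
  side <- character(0); tc <- numeric(0); xx <- numeric(0); yy <- numeric(0)
  s <- "L"; t <- 0.5; x <- 30
  repeat {
    y0 <- if (s == "L") d$bos / 2 else -d$bos / 2
    side <- c(side, s); tc <- c(tc, t); xx <- c(xx, x)
    yy <- c(yy, y0 + stats::rnorm(1) * 0.3)
    nL <- sum(side == "L"); nR <- sum(side == "R")
    if ((x > path_cm && nL >= min_contacts_per_side &&
         nR >= min_contacts_per_side) || length(side) >= max_contacts) break
    if (s == "L") {
      t <- t + max(d$step_time_R * (1 + stats::rnorm(1) * 0.02), 0.2)
      x <- x + max(d$step_len_R + stats::rnorm(1) * 1.5, 5)
      s <- "R"
    } else {
      t <- t + max(d$step_time_L * (1 + stats::rnorm(1) * 0.02), 0.2)
      x <- x + max(d$step_len_L + stats::rnorm(1) * 1.5, 5)
      s <- "L"
    }
  }
  n <- length(side)
  toff <- numeric(n)
  for (i in seq_len(n)) {
    swing_i <- if (side[i] == "L") d$wk_swing_L else d$wk_swing_R
    j <- which(side == side[i] & tc > tc[i])
    nxt <- if (length(j)) tc[min(j)] else tc[i] + stride_time
    toff[i] <- max(nxt - swing_i * (1 + stats::rnorm(1) * 0.02), tc[i] + 0.1)
  }
  data.frame(side = side, heel_x = xx, heel_y = yy,
             t_contact = tc, t_off = toff)
}

#' Simulate one trial
#'
#' @param profile A `subject_profile` from [simulate_subject()].
#' @param effects A `condition_effects` object.
#' @param trial_index Trial number within (subject, condition).
#' @param seed Root seed (the trial uses its own derived stream).
#' @param variance_split Between-subject fraction of total variance.
#' @return A `gait_trial` list with elements `imu` (an `imu_trial`),
#'   `walkway` (a `walkway_record`) and `truth` (a `gait_truth`).
#' @export
simulate_trial <- function(profile, effects, trial_index = 1L, seed = 1L,
                           variance_split = 0.6) {
  abort_if(!inherits(profile, "subject_profile"), "profile must be a subject_profile")
  abort_if(!inherits(effects, "condition_effects"), "effects must be a condition_effects")
  with_stream(seed, "trial", profile$subject_id, effects$condition, trial_index,
              expr = {
    d <- NULL
    for (i in seq_len(100L)) {
      d <- .draw_trial_drivers(profile, effects, variance_split)
      if (!is.null(d)) break
    }
    abort_if(is.null(d), "could not draw valid trial parameters in 100 attempts")
    imu <- .build_imu(d)
    wk <- .build_walkway(d)
    trial <- new_imu_trial(profile$subject_id, effects$condition, trial_index,
                           IMU_SAMPLE_RATE, imu$data)
    record <- new_walkway_record(profile$subject_id, effects$condition,
                                 trial_index, wk)
    truth <- new_gait_truth(profile$subject_id, effects$condition, trial_index,
                            imu$truth)
    structure(list(imu = trial, walkway = record, truth = truth,
                   subject_id = profile$subject_id,
                   condition = effects$condition,
                   trial_index = as.integer(trial_index)),
              class = "gait_trial")
  })
}

#' Simulate a full cohort
#'
#' @param config A [sim_config()].
#' @return A `gait_cohort`: list with `trials` (list of `gait_trial`),
#'   `subjects`, and `config`.
#' @examples
#' cohort <- simulate_cohort(sim_config(n_subjects = 2, n_trials = 1, seed = 7))
#' length(cohort$trials)  # 2 subjects x 3 conditions x 1 trial
#' @export
simulate_cohort <- function(config = sim_config()) {
  abort_if(!inherits(config, "sim_config"), "config must come from sim_config()")
  subjects <- lapply(seq_len(config$n_subjects),
                     function(i) simulate_subject(config$seed, i))
  eff <- lapply(stats::setNames(config$conditions, config$conditions),
                function(cond) {
    ov <- config$effects_overrides
    if (!is.null(ov) && "condition" %in% names(ov))
      ov <- ov[ov$condition == cond, setdiff(names(ov), "condition"), drop = FALSE]
    if (!is.null(ov) && nrow(ov) == 0L) ov <- NULL
    condition_effects(cond, overrides = ov)
  })
  trials <- list()
  for (p in subjects) {
    for (cond in config$conditions) {
      for (k in seq_len(config$n_trials)) {
        trials[[length(trials) + 1L]] <-
          simulate_trial(p, eff[[cond]], k, config$seed, config$variance_split)
      }
    }
  }
  structure(list(trials = trials, subjects = subjects, config = config),
            class = "gait_cohort")
}

#' @export
print.gait_cohort <- function(x, ...) {
  cat(sprintf("<gait_cohort> %d subjects x %s x %d trials = %d trials\n",
              x$config$n_subjects, paste(x$config$conditions, collapse = "/"),
              x$config$n_trials, length(x$trials)))
  invisible(x)
}
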