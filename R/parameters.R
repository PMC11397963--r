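# Gait parameter extraction: angular, spatio-temporal, and symmetry
# parameters per paired gait cycle (IMU) and per gait cycle anchored on the
# left foot (walkway).

#' Names of the IMU gait parameters (21)
#' @return Character vector of the 21 IMU parameter names.
#' @export
imu_parameter_names <- function() {
  per_leg <- c("shank_sagittal_angle", "thigh_sagittal_angle",
               "knee_sagittal_angle", "cycle_time", "cadence", "swing_time",
               "stance_time", "swing_phase", "stance_phase")
  c(paste0(rep(per_leg, each = 2), "_", c("L", "R")), "ssr1", "ssr2", "tsr")
}

#' Names of the walkway gait parameters (25)
#' @return Character vector of the 25 walkway parameter names.
#' @export
walkway_parameter_names <- function() {
  per_leg <- c("step_length", "stride_length", "base_of_support", "step_time",
               "stride_time", "swing_time", "stance_time",
               "single_support_time", "double_support_time", "stride_velocity",
               "swing_phase", "stance_phase")
  c(paste0(rep(per_leg, each = 2), "_", c("L", "R")), "tsr")
}

#' Angular range of motion over one cycle
#'
#' @param series Angle samples (degrees) within one gait cycle.
#' @return `max - min` in degrees (>= 0).
#' @export
angular_range <- function(series) {
  abort_if(length(series) == 0L || all(is.na(series)), "empty angle series")
  max(series, na.rm = TRUE) - min(series, na.rm = TRUE)
}

#' Temporal parameters of one gait cycle
#'
#' Cycle time is the duration between the two heel strikes; stance runs from
#' the first heel strike to toe-off and swing from toe-off to the second heel
#' strike. Phases are the corresponding fractions of cycle time and cadence
#' is 60 / cycle time (cycles per minute).
#'
#' @param t_hs1,t_to,t_hs2 Event times in seconds, `t_hs1 < t_to < t_hs2`.
#' @return Named list: `cycle_time`, `cadence`, `swing_time`, `stance_time`,
#'   `swing_phase`, `stance_phase`.
#' @export
temporal_parameters <- function(t_hs1, t_to, t_hs2) {
  abort_if(!(t_hs1 < t_to && t_to < t_hs2), "degenerate cycle: need HS1 < TO < HS2")
  cycle <- t_hs2 - t_hs1
  stance <- t_to - t_hs1
  swing <- t_hs2 - t_to
  list(cycle_time = cycle, cadence = 60 / cycle, swing_time = swing,
       stance_time = stance, swing_phase = swing / cycle,
       stance_phase = stance / cycle)
}

#' Temporal symmetry ratio
#'
#' Right-to-left ratio of the swing-to-stance time ratios. 1 indicates
#' perfect temporal symmetry; swapping legs maps the value to its
#' reciprocal.
#'
#' @param swing_r,stance_r,swing_l,stance_l Times in seconds (> 0).
#' @return The dimensionless ratio.
#' @export
tsr <- function(swing_r, stance_r, swing_l, stance_l) {
  abort_if(any(c(swing_r, stance_r, swing_l, stance_l) <= 0),
           "all swing/stance times must be > 0")
  (swing_r / stance_r) / (swing_l / stance_l)
}

#' Spatial symmetry ratio 1
#'
#' Right-to-left ratio of the shank-to-thigh sagittal range-of-motion ratios.
#'
#' @param shank_r,thigh_r,shank_l,thigh_l Ranges of motion in degrees.
#' @return The dimensionless ratio.
#' @export
ssr1 <- function(shank_r, thigh_r, shank_l, thigh_l) {
  abort_if(any(c(thigh_r, thigh_l, shank_l) <= 0), "zero denominator in SSR1")
  (shank_r / thigh_r) / (shank_l / thigh_l)
}

#' Spatial symmetry ratio 2
#'
#' Right-to-left ratio of the knee sagittal ranges of motion.
#'
#' @param knee_r,knee_l Knee ranges of motion in degrees.
#' @return The dimensionless ratio.
#' @export
ssr2 <- function(knee_r, knee_l) {
  abort_if(knee_l <= 0, "zero denominator in SSR2")
  knee_r / knee_l
}

#' Extract the 21 IMU gait parameters per cycle pair
#'
#' Angular ranges of motion are computed within each leg's own cycle window;
#' the knee sagittal angle is the per-sample difference between the thigh and
#' shank segment angles. Symmetry ratios combine the pair's left and right
#' values.
#'
#' @param trial An `imu_trial`.
#' @param pairs Cycle pairs from [pair_cycles()].
#' @return data.frame with one row per pair and the 21 columns of
#'   [imu_parameter_names()].
#' @export
extract_imu_parameters <- function(trial, pairs) {
  abort_if(!inherits(trial, "imu_trial"), "trial must be an imu_trial")
  abort_if(is.null(pairs) || nrow(pairs) == 0L, "need at least one cycle pair")
  d <- trial$data
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    p <- pairs[i, ]
    out <- list()
    for (leg in c("L", "R")) {
      w <- d$time >= p[[paste0("t_hs1_", leg)]] &
        d$time <= p[[paste0("t_hs2_", leg)]]
      abort_if(!any(w), "cycle window contains no samples")
      sh <- d[[paste0("angle_shank_", leg)]][w]
      th <- d[[paste0("angle_thigh_", leg)]][w]
      out[[paste0("shank_sagittal_angle_", leg)]] <- angular_range(sh)
      out[[paste0("thigh_sagittal_angle_", leg)]] <- angular_range(th)
      out[[paste0("knee_sagittal_angle_", leg)]] <- angular_range(th - sh)
      tp <- temporal_parameters(p[[paste0("t_hs1_", leg)]],
                                p[[paste0("t_to_", leg)]],
                                p[[paste0("t_hs2_", leg)]])
      for (nm in names(tp)) out[[paste0(nm, "_", leg)]] <- tp[[nm]]
    }
    out$ssr1 <- ssr1(out$shank_sagittal_angle_R, out$thigh_sagittal_angle_R,
                     out$shank_sagittal_angle_L, out$thigh_sagittal_angle_L)
    out$ssr2 <- ssr2(out$knee_sagittal_angle_R, out$knee_sagittal_angle_L)
    out$tsr <- tsr(out$swing_time_R, out$stance_time_R,
                   out$swing_time_L, out$stance_time_L)
    as.data.frame(out)
  })
  res <- do.call(rbind, rows)
  res[, imu_parameter_names()]
}

# time during [a1, a2] when the given foot is on the ground
.ground_time <- function(a1, a2, contacts, offs) {
  interval_overlap(a1, a2, contacts, offs)
}

#' Extract the 25 walkway gait parameters per gait cycle
#'
#' One output row per left-anchored gait cycle (a left footfall with a
#' following left footfall). Step length is the along-walkway distance
#' between consecutive opposite-foot heel positions, stride length between
#' consecutive same-foot heel positions, and base of support the lateral
#' distance between a heel and the least-squares line of progression of the
#' opposite foot's heels. Stance is first contact to last contact of a
#' footfall, swing the remainder of the stride; single support is the time
#' only that foot is on the ground within its stride and double support the
#' time both feet are. Right-leg fields come from the right stride beginning
#' inside the left cycle; where the record is too short to complete them
#' they are `NA`.
#'
#' @param record A `walkway_record`.
#' @return data.frame with one row per left-anchored cycle and the 25 columns
#'   of [walkway_parameter_names()].
#' @export
extract_walkway_parameters <- function(record) {
  abort_if(!inherits(record, "walkway_record"), "record must be a walkway_record")
  ff <- record$footfalls[order(record$footfalls$t_contact), , drop = FALSE]
  abort_if(nrow(ff) < 3L, "need at least 3 footfalls")
  abort_if(any(ff$side[-1] == ff$side[-nrow(ff)]),
           "footfalls must alternate sides")

  # least-squares line of progression per foot: heel_y as a function of
  # heel_x; with a single heel, the line is horizontal through it
  prog_line <- function(side) {
    sub <- ff[ff$side == side, , drop = FALSE]
    if (nrow(sub) < 2L) return(c(intercept = sub$heel_y[1], slope = 0))
    fit <- stats::lm.fit(cbind(1, sub$heel_x), sub$heel_y)
    c(intercept = fit$coefficients[1], slope = fit$coefficients[2])
  }
  line_of <- list(L = prog_line("L"), R = prog_line("R"))
  lateral_dist <- function(x, y, line) {
    abs(y - (line[1] + line[2] * x)) / sqrt(1 + line[2]^2)
  }

  idx <- seq_len(nrow(ff))
  stride_of <- function(i) {
    # stride = footfall i to next same-side footfall (i + 2 under alternation)
    j <- i + 2L
    if (j > nrow(ff)) return(NULL)
    list(i = i, j = j, side = ff$side[i],
         t1 = ff$t_contact[i], t2 = ff$t_contact[j],
         stride_time = ff$t_contact[j] - ff$t_contact[i],
         stride_length = ff$heel_x[j] - ff$heel_x[i],
         stance = ff$t_off[i] - ff$t_contact[i])
  }

  # Fields for the footfall at index i (side known from alternation). The
  # footfall-level quantities (step geometry, base of support, stance and
  # support times) only need the footfall itself; quantities spanning a full
  # stride (stride length/time/velocity, swing, phases) additionally need
  # the next same-side footfall and are NA when the record ends first.
  leg_fields <- function(i, opp_side) {
    na12 <- stats::setNames(as.list(rep(NA_real_, 12)),
      c("step_length", "stride_length", "base_of_support", "step_time",
        "stride_time", "swing_time", "stance_time", "single_support_time",
        "double_support_time", "stride_velocity", "swing_phase",
        "stance_phase"))
    if (is.na(i) || i > nrow(ff)) return(na12)
    out <- na12
    prev_opp <- i - 1L  # footfall before i is the opposite foot (alternation)
    if (prev_opp >= 1L) {
      out$step_length <- ff$heel_x[i] - ff$heel_x[prev_opp]
      out$step_time <- ff$t_contact[i] - ff$t_contact[prev_opp]
    }
    out$base_of_support <- lateral_dist(ff$heel_x[i], ff$heel_y[i],
                                        line_of[[opp_side]])
    stance <- ff$t_off[i] - ff$t_contact[i]
    out$stance_time <- stance
    opp <- ff$side == opp_side
    on_opp <- .ground_time(ff$t_contact[i], ff$t_off[i],
                           ff$t_contact[opp], ff$t_off[opp])
    out$single_support_time <- stance - on_opp  # alone on the ground
    out$double_support_time <- on_opp           # both feet down, own stance
    s <- stride_of(i)
    if (!is.null(s)) {
      out$stride_length <- s$stride_length
      out$stride_time <- s$stride_time
      out$swing_time <- s$stride_time - stance
      out$stride_velocity <- s$stride_length / s$stride_time
      out$swing_phase <- out$swing_time / s$stride_time
      out$stance_phase <- stance / s$stride_time
    }
    out
  }

  left_starts <- idx[ff$side == "L" & idx + 2L <= nrow(ff)]
  abort_if(length(left_starts) == 0L && !any(ff$side == "L"),
           "record has no left footfalls")
  rows <- lapply(left_starts, function(i) {
    fl <- leg_fields(i, "R")
    fr <- leg_fields(i + 1L, "L")  # right footfall inside the left cycle
    out <- list()
    for (nm in names(fl)) {
      out[[paste0(nm, "_L")]] <- fl[[nm]]
      out[[paste0(nm, "_R")]] <- fr[[nm]]
    }
    times <- c(fl$swing_time, fl$stance_time, fr$swing_time, fr$stance_time)
    out$tsr <- if (!anyNA(times) && all(times > 0))
      tsr(fr$swing_time, fr$stance_time, fl$swing_time, fl$stance_time)
    else NA_real_
    as.data.frame(out)
  })
  abort_if(length(rows) == 0L, "record too short for a complete left stride")
  res <- do.call(rbind, rows)
  res[, walkway_parameter_names()]
}

#' Per-cycle parameter table for a whole cohort
#'
#' Runs event detection (IMU) or footfall geometry (walkway) on every trial
#' and returns one row per cycle pair / gait cycle with key columns
#' (`subject_id`, `condition`, `trial_index`, `cycle_index`) plus the named
#' parameters. Incomplete walkway rows (NA in any parameter) are dropped.
#'
#' @param cohort A `gait_cohort`.
#' @param system `"imu"` or `"walkway"`.
#' @param ... Passed to [detect_events()] for the IMU system.
#' @return data.frame of keys + 21 or 25 parameter columns.
#' @export
cohort_parameter_table <- function(cohort, system = c("imu", "walkway"), ...) {
  abort_if(!inherits(cohort, "gait_cohort"), "cohort must be a gait_cohort")
  system <- match.arg(system)
  rows <- lapply(cohort$trials, function(tr) {
    pars <- if (system == "imu") {
      seg <- segment_trial(tr$imu, ...)
      if (nrow(seg$pairs) == 0L) return(NULL)
      extract_imu_parameters(tr$imu, seg$pairs)
    } else {
      p <- extract_walkway_parameters(tr$walkway)
      p <- p[stats::complete.cases(p), , drop = FALSE]
      if (nrow(p) == 0L) return(NULL)
      p
    }
    cbind(data.frame(subject_id = tr$subject_id, condition = tr$condition,
                     trial_index = tr$trial_index,
                     cycle_index = seq_len(nrow(pars))), pars)
  })
  out <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  rownames(out) <- NULL
  out
}
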