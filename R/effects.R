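# Condition-effect reference table and accessors.
#
# The table holds, for every gait parameter of both measurement systems and
# for each walking condition (normal, knee brace, ankle brace), the target
# cohort mean and standard deviation used to calibrate the synthetic
# generator. Angular ranges are in degrees, times in seconds, lengths in cm,
# cadence in strides per minute, ratios dimensionless. SDs are total
# (between-subject + within-subject) spreads.

.effects_rows <- function() {
  # param, side, normal mean, normal sd, knee mean, knee sd, ankle mean, ankle sd
  imu <- list(
    list("shank_sagittal_angle", "L", 68.51, 5.06, 63.98, 5.36, 59.51, 5.58),
    list("shank_sagittal_angle", "R", 66.99, 5.00, 47.66, 5.33, 51.14, 12.30),
    list("thigh_sagittal_angle", "L", 35.27, 4.31, 34.24, 3.25, 34.30, 3.90),
    list("thigh_sagittal_angle", "R", 36.26, 4.72, 38.96, 4.22, 37.18, 5.70),
    list("knee_sagittal_angle",  "L", 57.57, 5.87, 53.74, 5.95, 49.77, 6.60),
    list("knee_sagittal_angle",  "R", 55.63, 6.97, 12.81, 4.88, 36.68, 14.58),
    list("cycle_time",   "L", 1.12, 0.04, 1.25, 0.12, 1.33, 0.12),
    list("cycle_time",   "R", 1.12, 0.05, 1.25, 0.12, 1.33, 0.13),
    list("cadence",      "L", 53.83, 2.13, 48.53, 4.61, 45.40, 4.33),
    list("cadence",      "R", 53.71, 2.35, 48.57, 4.67, 45.41, 4.45),
    list("swing_time",   "L", 0.49, 0.03, 0.49, 0.03, 0.48, 0.04),
    list("swing_time",   "R", 0.49, 0.02, 0.61, 0.07, 0.59, 0.06),
    list("stance_time",  "L", 0.63, 0.03, 0.76, 0.11, 0.86, 0.10),
    list("stance_time",  "R", 0.63, 0.04, 0.64, 0.06, 0.74, 0.08),
    list("swing_phase",  "L", 0.44, 0.02, 0.40, 0.03, 0.36, 0.03),
    list("swing_phase",  "R", 0.44, 0.01, 0.49, 0.03, 0.44, 0.03),
    list("stance_phase", "L", 0.56, 0.02, 0.60, 0.03, 0.64, 0.03),
    list("stance_phase", "R", 0.56, 0.01, 0.51, 0.03, 0.56, 0.03),
    list("ssr1", "",  0.96, 0.10, 0.66, 0.07, 0.79, 0.14),
    list("ssr2", "",  0.98, 0.15, 0.24, 0.08, 0.75, 0.34),
    list("tsr",  "",  1.00, 0.08, 1.49, 0.29, 1.45, 0.28))
  wk <- list(
    list("step_length",     "L", 63.89, 4.26, 56.56, 5.16, 49.28, 8.49),
    list("step_length",     "R", 63.67, 4.55, 57.63, 4.72, 55.48, 5.65),
    list("stride_length",   "L", 128.04, 8.89, 114.89, 8.48, 105.40, 12.37),
    list("stride_length",   "R", 128.05, 8.72, 114.30, 8.54, 104.70, 12.27),
    list("base_of_support", "L", 11.59, 3.14, 17.59, 4.28, 18.83, 3.32),
    list("base_of_support", "R", 11.63, 3.11, 17.44, 4.43, 18.68, 3.23),
    list("step_time",       "L", 0.57, 0.03, 0.59, 0.04, 0.63, 0.07),
    list("step_time",       "R", 0.57, 0.03, 0.67, 0.08, 0.72, 0.08),
    list("stride_time",     "L", 1.13, 0.05, 1.25, 0.12, 1.35, 0.13),
    list("stride_time",     "R", 1.13, 0.05, 1.26, 0.12, 1.35, 0.13),
    list("stride_velocity", "L", 113.75, 9.98, 92.89, 14.27, 79.11, 13.07),
    list("stride_velocity", "R", 113.95, 10.01, 92.09, 14.40, 78.56, 13.12),
    list("double_support_time", "L", 0.26, 0.02, 0.29, 0.05, 0.38, 0.06),
    list("double_support_time", "R", 0.26, 0.03, 0.29, 0.05, 0.38, 0.06),
    list("single_support_time", "L", 0.43, 0.02, 0.54, 0.07, 0.54, 0.06),
    list("single_support_time", "R", 0.43, 0.02, 0.43, 0.03, 0.43, 0.05),
    list("swing_time",   "L", 0.43, 0.02, 0.43, 0.03, 0.43, 0.05),
    list("swing_time",   "R", 0.43, 0.02, 0.54, 0.07, 0.54, 0.06),
    list("stance_time",  "L", 0.70, 0.04, 0.82, 0.11, 0.92, 0.10),
    list("stance_time",  "R", 0.70, 0.04, 0.72, 0.06, 0.80, 0.09),
    list("swing_phase",  "L", 0.38, 0.01, 0.35, 0.03, 0.32, 0.03),
    list("swing_phase",  "R", 0.38, 0.01, 0.42, 0.02, 0.40, 0.03),
    list("stance_phase", "L", 0.62, 0.01, 0.65, 0.03, 0.68, 0.03),
    list("stance_phase", "R", 0.62, 0.01, 0.58, 0.02, 0.60, 0.03),
    list("tsr", "", 1.00, 0.06, 1.41, 0.23, 1.50, 0.33))
  build <- function(rows, system) {
    do.call(rbind, lapply(rows, function(r) {
      data.frame(system = system, parameter = r[[1]], side = r[[2]],
                 condition = c("normal", "knee", "ankle"),
                 mean = c(r[[3]], r[[5]], r[[7]]),
                 sd   = c(r[[4]], r[[6]], r[[8]]),
                 stringsAsFactors = FALSE)
    }))
  }
  rbind(build(imu, "imu"), build(wk, "walkway"))
}

.effects_cache <- new.env(parent = emptyenv())

#' Reference condition-effect table
#'
#' Target mean and standard deviation of every gait parameter under the three
#' walking conditions (normal, knee-brace, ankle-brace), for both the
#' IMU-based and walkway systems. These targets drive the synthetic gait
#' generator; a subset of "driver" parameters is drawn directly and the
#' remaining parameters emerge from the placement/waveform model.
#'
#' @return A data.frame with columns `system`, `parameter`, `side`,
#'   `condition`, `mean`, `sd`.
#' @export
default_condition_effects <- function() {
  if (is.null(.effects_cache$table)) .effects_cache$table <- .effects_rows()
  .effects_cache$table
}

#' Condition effects for one walking condition
#'
#' @param condition One of `"normal"`, `"knee"`, `"ankle"`.
#' @param overrides Optional data.frame with columns `system`, `parameter`,
#'   `side`, and `mean` and/or `sd`, replacing individual cells of the
#'   reference table for this condition.
#' @return An object of class `condition_effects`: a list with the condition
#'   name and the effect table restricted to that condition.
#' @export
condition_effects <- function(condition = c("normal", "knee", "ankle"),
                              overrides = NULL) {
  condition <- match.arg(condition)
  tab <- default_condition_effects()
  tab <- tab[tab$condition == condition, , drop = FALSE]
  rownames(tab) <- NULL
  if (!is.null(overrides)) {
    abort_if(!is.data.frame(overrides) ||
               !all(c("system", "parameter", "side") %in% names(overrides)),
             "overrides must be a data.frame with system/parameter/side columns")
    for (i in seq_len(nrow(overrides))) {
      o <- overrides[i, ]
      j <- which(tab$system == o$system & tab$parameter == o$parameter &
                   tab$side == o$side)
      abort_if(length(j) != 1L, "override does not match a unique row: %s/%s/%s",
               o$system, o$parameter, o$side)
      if (!is.null(o$mean) && !is.na(o$mean)) tab$mean[j] <- o$mean
      if (!is.null(o$sd)   && !is.na(o$sd))   tab$sd[j]   <- o$sd
    }
  }
  abort_if(any(tab$sd <= 0), "all effect SDs must be > 0")
  out <- structure(list(condition = condition, table = tab),
                   class = "condition_effects")
  out
}

# Look up target mean/sd for one cell of a condition_effects object.
effect_cell <- function(effects, system, parameter, side = "") {
  tab <- effects$table
  j <- which(tab$system == system & tab$parameter == parameter & tab$side == side)
  abort_if(length(j) != 1L, "no effect entry for %s/%s/%s", system, parameter, side)
  c(mean = tab$mean[j], sd = tab$sd[j])
}

#' Check the right-knee range-of-motion ordering across conditions
#'
#' The right (braced) knee sagittal range of motion must be smallest under the
#' knee condition, intermediate under the ankle condition, and largest under
#' normal walking.
#'
#' @param normal,knee,ankle `condition_effects` objects for the three
#'   conditions (defaults: reference tables).
#' @return Invisibly `TRUE`; errors if the ordering is violated.
#' @export
check_effect_ordering <- function(normal = condition_effects("normal"),
                                  knee = condition_effects("knee"),
                                  ankle = condition_effects("ankle")) {
  v <- c(knee  = effect_cell(knee,  "imu", "knee_sagittal_angle", "R")[["mean"]],
         ankle = effect_cell(ankle, "imu", "knee_sagittal_angle", "R")[["mean"]],
         normal = effect_cell(normal, "imu", "knee_sagittal_angle", "R")[["mean"]])
  abort_if(!(v[["knee"]] < v[["ankle"]] && v[["ankle"]] < v[["normal"]]),
           "right knee ROM must satisfy knee < ankle < normal (got %s)",
           paste(round(v, 2), collapse = " / "))
  invisible(TRUE)
}
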