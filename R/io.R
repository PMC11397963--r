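# Typed containers and tabular input/output.
#
# Dialect: comma-separated, UTF-8, header row, "." decimal separator. One
# file per trial plus a cohort index file. Times are seconds, angles degrees,
# angular velocities degrees per second, positions centimetres.

IMU_CHANNELS <- c("time", "angle_thigh_L", "angle_thigh_R",
                  "angle_shank_L", "angle_shank_R",
                  "angvel_shank_L", "angvel_shank_R")
WALKWAY_COLUMNS <- c("side", "heel_x", "heel_y", "t_contact", "t_off")

#' Construct an IMU trial object
#'
#' @param subject_id,condition,trial_index Trial keys.
#' @param sample_rate Sampling rate in Hz.
#' @param data data.frame with columns `time`, `angle_thigh_L/R`,
#'   `angle_shank_L/R`, `angvel_shank_L/R`.
#' @param meta Optional named list of extra metadata.
#' @return An `imu_trial` object.
#' @export
new_imu_trial <- function(subject_id, condition, trial_index, sample_rate,
                          data, meta = list()) {
  missing_cols <- setdiff(IMU_CHANNELS, names(data))
  abort_if(length(missing_cols) > 0, "missing IMU column(s): %s",
           paste(missing_cols, collapse = ", "))
  abort_if(nrow(data) < 2L, "IMU trial needs at least 2 samples")
  dt <- diff(data$time)
  abort_if(any(dt <= 0), "IMU time column must be strictly increasing")
  abort_if(any(abs(dt - 1 / sample_rate) > 0.01 / sample_rate),
           "IMU time column must be uniform at 1/sample_rate within 1%%")
  structure(list(subject_id = subject_id, condition = condition,
                 trial_index = as.integer(trial_index),
                 sample_rate = sample_rate,
                 data = data[, IMU_CHANNELS], meta = meta),
            class = "imu_trial")
}

#' @export
print.imu_trial <- function(x, ...) {
  cat(sprintf("<imu_trial> %s/%s/trial %d: %d samples @ %g Hz (%.2f s)\n",
              x$subject_id, x$condition, x$trial_index, nrow(x$data),
              x$sample_rate, nrow(x$data) / x$sample_rate))
  invisible(x)
}

#' Construct a walkway footfall record
#'
#' @inheritParams new_imu_trial
#' @param footfalls data.frame with columns `side` ("L"/"R"), `heel_x`
#'   (along-walkway position, cm), `heel_y` (lateral position, cm),
#'   `t_contact`, `t_off` (s).
#' @return A `walkway_record` object.
#' @export
new_walkway_record <- function(subject_id, condition, trial_index, footfalls,
                               meta = list()) {
  missing_cols <- setdiff(WALKWAY_COLUMNS, names(footfalls))
  abort_if(length(missing_cols) > 0, "missing walkway column(s): %s",
           paste(missing_cols, collapse = ", "))
  abort_if(nrow(footfalls) == 0L, "no footfalls")
  abort_if(!all(footfalls$side %in% c("L", "R")), "side must be 'L' or 'R'")
  abort_if(any(footfalls$t_off <= footfalls$t_contact),
           "every footfall needs t_off > t_contact")
  for (s in c("L", "R")) {
    tcs <- footfalls$t_contact[footfalls$side == s]
    abort_if(is.unsorted(tcs, strictly = TRUE),
             "t_contact must be strictly increasing per side")
  }
  structure(list(subject_id = subject_id, condition = condition,
                 trial_index = as.integer(trial_index),
                 footfalls = footfalls[, WALKWAY_COLUMNS], meta = meta),
            class = "walkway_record")
}

#' @export
print.walkway_record <- function(x, ...) {
  cat(sprintf("<walkway_record> %s/%s/trial %d: %d footfalls over %.0f cm\n",
              x$subject_id, x$condition, x$trial_index, nrow(x$footfalls),
              diff(range(x$footfalls$heel_x))))
  invisible(x)
}

#' Construct a ground-truth event set
#'
#' @inheritParams new_imu_trial
#' @param events data.frame with columns `leg`, `type` ("HS"/"TO"), `time`.
#' @return A `gait_truth` object. Events must strictly increase in time and
#'   alternate HS/TO within each leg.
#' @export
new_gait_truth <- function(subject_id, condition, trial_index, events) {
  abort_if(!all(c("leg", "type", "time") %in% names(events)),
           "events need leg/type/time columns")
  for (l in unique(events$leg)) {
    ev <- events[events$leg == l, ]
    ev <- ev[order(ev$time), ]
    abort_if(is.unsorted(ev$time, strictly = TRUE),
             "ground-truth times must strictly increase per leg")
    abort_if(any(ev$type[-1] == ev$type[-nrow(ev)]),
             "ground-truth HS/TO must alternate per leg")
  }
  structure(list(subject_id = subject_id, condition = condition,
                 trial_index = as.integer(trial_index),
                 events = events,
                 cycle_count = vapply(c(L = "L", R = "R"), function(l)
                   max(0L, sum(events$leg == l & events$type == "HS") - 1L),
                   0L)),
            class = "gait_truth")
}

#' Write / read an IMU trial table
#'
#' Round-trip write-then-read reproduces all channel values to 6 decimals.
#' Extra columns in a file are preserved in the trial's `meta$extra`.
#'
#' @param trial An `imu_trial`.
#' @param path File path (.csv).
#' @return `read_imu_table` returns an `imu_trial`; `write_imu_table` returns
#'   `path` invisibly.
#' @export
write_imu_table <- function(trial, path) {
  abort_if(!inherits(trial, "imu_trial"), "trial must be an imu_trial")
  out <- data.table::as.data.table(trial$data)
  out <- cbind(data.table::data.table(subject_id = trial$subject_id,
                                      condition = trial$condition,
                                      trial_index = trial$trial_index,
                                      sample_rate = trial$sample_rate), out)
  data.table::fwrite(out, path)
  invisible(path)
}

#' @rdname write_imu_table
#' @export
read_imu_table <- function(path) {
  abort_if(!file.exists(path), "file does not exist: %s", path)
  dt <- data.table::fread(path, data.table = FALSE)
  keys <- c("subject_id", "condition", "trial_index", "sample_rate")
  missing_cols <- setdiff(c(keys, IMU_CHANNELS), names(dt))
  abort_if(length(missing_cols) > 0, "schema error, missing column(s): %s",
           paste(missing_cols, collapse = ", "))
  extra <- setdiff(names(dt), c(keys, IMU_CHANNELS))
  abort_if(any(diff(dt$time) <= 0), "data error: non-monotone time")
  new_imu_trial(dt$subject_id[1], dt$condition[1], dt$trial_index[1],
                dt$sample_rate[1], dt[, IMU_CHANNELS],
                meta = if (length(extra)) list(extra = dt[, extra, drop = FALSE])
                       else list())
}

#' Write / read a walkway footfall table
#'
#' @param record A `walkway_record`.
#' @param path File path (.csv).
#' @return `read_walkway_table` returns a `walkway_record`;
#'   `write_walkway_table` returns `path` invisibly.
#' @export
write_walkway_table <- function(record, path) {
  abort_if(!inherits(record, "walkway_record"), "record must be a walkway_record")
  out <- cbind(data.table::data.table(subject_id = record$subject_id,
                                      condition = record$condition,
                                      trial_index = record$trial_index),
               data.table::as.data.table(record$footfalls))
  data.table::fwrite(out, path)
  invisible(path)
}

#' @rdname write_walkway_table
#' @export
read_walkway_table <- function(path) {
  abort_if(!file.exists(path), "file does not exist: %s", path)
  dt <- data.table::fread(path, data.table = FALSE)
  keys <- c("subject_id", "condition", "trial_index")
  missing_cols <- setdiff(c(keys, WALKWAY_COLUMNS), names(dt))
  abort_if(length(missing_cols) > 0, "schema error, missing column(s): %s",
           paste(missing_cols, collapse = ", "))
  abort_if(nrow(dt) == 0L, "data error: no footfalls")
  new_walkway_record(dt$subject_id[1], dt$condition[1], dt$trial_index[1],
                     dt[, WALKWAY_COLUMNS])
}

#' Write / read a ground-truth or detected event table
#'
#' One row per event: subject, condition, trial, leg, event type, time (s),
#' and (for detected events) sample index.
#'
#' @param events data.frame of events with key columns.
#' @param path File path (.csv).
#' @export
write_events_table <- function(events, path) {
  data.table::fwrite(data.table::as.data.table(events), path)
  invisible(path)
}

#' @rdname write_events_table
#' @export
read_events_table <- function(path) {
  abort_if(!file.exists(path), "file does not exist: %s", path)
  data.table::fread(path, data.table = FALSE)
}

#' Write a cohort to a directory of per-trial tables
#'
#' Writes one IMU table and one walkway table per trial, a ground-truth
#' events table, and a cohort index file; all comma-separated text.
#'
#' @param cohort A `gait_cohort`.
#' @param dir Output directory (created if missing).
#' @return The directory, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  abort_if(!inherits(cohort, "gait_cohort"), "cohort must be a gait_cohort")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  idx <- list(); evs <- list()
  for (tr in cohort$trials) {
    stem <- sprintf("%s_%s_t%02d", tr$subject_id, tr$condition, tr$trial_index)
    write_imu_table(tr$imu, file.path(dir, paste0(stem, "_imu.csv")))
    write_walkway_table(tr$walkway, file.path(dir, paste0(stem, "_walkway.csv")))
    idx[[length(idx) + 1L]] <- data.frame(
      subject_id = tr$subject_id, condition = tr$condition,
      trial_index = tr$trial_index,
      imu_file = paste0(stem, "_imu.csv"),
      walkway_file = paste0(stem, "_walkway.csv"))
    ev <- tr$truth$events
    evs[[length(evs) + 1L]] <- cbind(
      data.frame(subject_id = tr$subject_id, condition = tr$condition,
                 trial_index = tr$trial_index), ev)
  }
  data.table::fwrite(data.table::rbindlist(idx), file.path(dir, "cohort_index.csv"))
  write_events_table(data.table::rbindlist(evs),
                     file.path(dir, "ground_truth_events.csv"))
  invisible(dir)
}

#' Read a cohort directory written by [write_cohort()]
#'
#' @param dir Directory containing `cohort_index.csv`.
#' @return A `gait_cohort` (without subject profiles or config; trials carry
#'   their ground truth when `ground_truth_events.csv` is present).
#' @export
read_cohort <- function(dir) {
  index_path <- file.path(dir, "cohort_index.csv")
  abort_if(!file.exists(index_path), "missing input: %s", index_path)
  idx <- data.table::fread(index_path, data.table = FALSE)
  truth_path <- file.path(dir, "ground_truth_events.csv")
  truth_all <- if (file.exists(truth_path)) read_events_table(truth_path) else NULL
  trials <- lapply(seq_len(nrow(idx)), function(i) {
    imu <- read_imu_table(file.path(dir, idx$imu_file[i]))
    wk <- read_walkway_table(file.path(dir, idx$walkway_file[i]))
    truth <- NULL
    if (!is.null(truth_all)) {
      ev <- truth_all[truth_all$subject_id == idx$subject_id[i] &
                        truth_all$condition == idx$condition[i] &
                        truth_all$trial_index == idx$trial_index[i],
                      c("leg", "type", "time")]
      if (nrow(ev)) truth <- new_gait_truth(idx$subject_id[i], idx$condition[i],
                                            idx$trial_index[i], ev)
    }
    structure(list(imu = imu, walkway = wk, truth = truth,
                   subject_id = idx$subject_id[i], condition = idx$condition[i],
                   trial_index = idx$trial_index[i]),
              class = "gait_trial")
  })
  structure(list(trials = trials, subjects = NULL, config = NULL),
            class = "gait_cohort")
}

#' Read an analysis configuration file
#'
#' YAML (or JSON, which YAML subsumes) key-value file with any of:
#' `n_subjects`, `n_trials`, `seed`, `variance_split`, `conditions`,
#' `effects_overrides` (list of records with system/parameter/side/mean/sd).
#'
#' @param path Configuration file path.
#' @return A [sim_config()].
#' @export
read_sim_config <- function(path) {
  abort_if(!file.exists(path), "file does not exist: %s", path)
  cfg <- yaml::read_yaml(path)
  ov <- cfg$effects_overrides
  if (!is.null(ov)) ov <- do.call(rbind, lapply(ov, as.data.frame))
  sim_config(n_subjects = cfg$n_subjects %||% 10L,
             n_trials = cfg$n_trials %||% 10L,
             seed = cfg$seed %||% 1L,
             variance_split = cfg$variance_split %||% 0.6,
             conditions = unlist(cfg$conditions) %||% c("normal", "knee", "ankle"),
             effects_overrides = ov)
}

#' Write a stage manifest
#'
#' Records the stage name, seed, configuration hash, package and R versions,
#' and input/output paths so a run can be reproduced.
#'
#' @param stage Stage name.
#' @param path Output JSON path.
#' @param seed Seed in effect.
#' @param config Configuration object (hashed into the manifest).
#' @param inputs,outputs Character vectors of file paths.
#' @export
write_manifest <- function(stage, path, seed = NA, config = NULL,
                           inputs = character(0), outputs = character(0)) {
  cfg_hash <- if (is.null(config)) NA_character_ else {
    raw <- serialize(config, NULL, version = 2)
    # small polynomial content hash; stable across sessions
    h <- 0
    for (b in as.integer(raw)) h <- (h * 257 + b) %% 2147483647
    sprintf("%08x", h)
  }
  manifest <- list(stage = stage, seed = seed, config_hash = cfg_hash,
                   package_version = as.character(utils::packageVersion("imugait")),
                   r_version = R.version.string,
                   inputs = inputs, outputs = outputs,
                   timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
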