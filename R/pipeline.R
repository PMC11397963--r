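# End-to-end pipeline stages with run manifests, plus a command-line style
# dispatcher. Each stage is a pure function of (inputs, config, seed) and
# writes its outputs together with a JSON manifest.

#' Run the full analysis pipeline
#'
#' Chains simulation, event detection, parameter extraction, classification
#' and the statistical post-analysis, writing each stage's tables and a JSON
#' run manifest under `out_dir`.
#'
#' @param config A [sim_config()].
#' @param out_dir Output directory.
#' @param tasks Classification tasks to run (see [build_feature_matrix()]).
#' @param classifiers Classifier families to run.
#' @param systems Measurement systems to analyse.
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list with the parameter tables, the classification
#'   summary table, and the descriptive reports.
#' @export
run_pipeline <- function(config = sim_config(), out_dir,
                         tasks = "three-class", classifiers = "rf",
                         systems = c("imu", "walkway"), quiet = FALSE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message(sprintf(...))
  t0 <- Sys.time()

  say("simulate: %d subjects x %d trials x %s", config$n_subjects,
      config$n_trials, paste(config$conditions, collapse = "/"))
  cohort <- simulate_cohort(config)
  sim_dir <- file.path(out_dir, "simulated")
  write_cohort(cohort, sim_dir)
  write_manifest("simulate", file.path(out_dir, "manifest_simulate.json"),
                 seed = config$seed, config = config, outputs = sim_dir)

  say("detect: %d trials", length(cohort$trials))
  det <- lapply(cohort$trials, function(tr) {
    seg <- segment_trial(tr$imu)
    cbind(data.frame(subject_id = tr$subject_id, condition = tr$condition,
                     trial_index = tr$trial_index), seg$events)
  })
  events_path <- file.path(out_dir, "detected_events.csv")
  write_events_table(data.table::rbindlist(det), events_path)
  write_manifest("detect", file.path(out_dir, "manifest_detect.json"),
                 seed = config$seed, config = config, inputs = sim_dir,
                 outputs = events_path)

  say("extract: gait parameters")
  feats <- list()
  for (sys in systems) {
    feats[[sys]] <- cohort_parameter_table(cohort, sys)
    data.table::fwrite(feats[[sys]],
                       file.path(out_dir, sprintf("parameters_%s.csv", sys)))
  }
  write_manifest("extract", file.path(out_dir, "manifest_extract.json"),
                 seed = config$seed, config = config,
                 outputs = file.path(out_dir, sprintf("parameters_%s.csv", systems)))

  say("classify: %s x %s x %s", paste(systems, collapse = "/"),
      paste(tasks, collapse = "/"), paste(classifiers, collapse = "/"))
  summaries <- list(); fold_tables <- list(); confusions <- list()
  for (sys in systems) for (task in tasks) for (cl in classifiers) {
    res <- run_task(feats[[sys]], task, sys, classifier_spec(cl),
                    seed = config$seed)
    summaries[[length(summaries) + 1L]] <- res$summary
    ft <- res$report$per_fold
    ft$system <- sys; ft$task <- task; ft$classifier <- cl
    fold_tables[[length(fold_tables) + 1L]] <- ft
    cm <- as.data.frame(as.table(res$report$confusion))
    names(cm) <- c("true", "predicted", "count")
    cm$system <- sys; cm$task <- task; cm$classifier <- cl
    confusions[[length(confusions) + 1L]] <- cm
  }
  summary_tab <- do.call(rbind, summaries)
  data.table::fwrite(summary_tab, file.path(out_dir, "classification_summary.csv"))
  data.table::fwrite(data.table::rbindlist(fold_tables),
                     file.path(out_dir, "classification_folds.csv"))
  data.table::fwrite(data.table::rbindlist(confusions),
                     file.path(out_dir, "confusion_matrices.csv"))
  write_manifest("classify", file.path(out_dir, "manifest_classify.json"),
                 seed = config$seed, config = config,
                 outputs = file.path(out_dir, "classification_summary.csv"))

  say("stats: descriptive report + pairwise tests")
  reports <- list()
  for (sys in systems) {
    reports[[sys]] <- descriptive_report(feats[[sys]], pairwise = TRUE)
    data.table::fwrite(reports[[sys]],
                       file.path(out_dir, sprintf("descriptives_%s.csv", sys)))
  }
  write_manifest("stats", file.path(out_dir, "manifest_stats.json"),
                 seed = config$seed, config = config,
                 outputs = file.path(out_dir, sprintf("descriptives_%s.csv", systems)))

  say("done in %.1f s", as.numeric(difftime(Sys.time(), t0, units = "secs")))
  invisible(list(parameters = feats, classification = summary_tab,
                 descriptives = reports))
}

# minimal flag parser: --name value pairs after the subcommand
.parse_flags <- function(args) {
  flags <- list()
  i <- 1L
  while (i <= length(args)) {
    abort_if(!startsWith(args[i], "--"), "unexpected argument: %s", args[i])
    abort_if(i + 1L > length(args), "flag %s needs a value", args[i])
    flags[[substring(args[i], 3)]] <- args[i + 1L]
    i <- i + 2L
  }
  flags
}

#' Command-line entry point
#'
#' Dispatches the pipeline stages from an argument vector, e.g.
#' `gait_cli(c("simulate", "--seed", "1", "--out", "runs/d1"))`. Commands:
#' `simulate`, `detect`, `extract`, `classify`, `stats`, `run-all`.
#' Shared flags: `--config` (YAML), `--seed`, `--out`; `classify` also takes
#' `--system`, `--task`, `--classifier` (value `all` expands to every
#' option). A thin Rscript wrapper is installed under `inst/cli/`.
#'
#' @param args Character vector of command-line arguments.
#' @return Exit status, 0 on success (invisibly).
#' @export
gait_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: imugait <command> [--config file] [--seed n] [--out dir]",
    "                         [--system imu|walkway|both] [--task ...]",
    "                         [--classifier svm|rf|xgb|all]",
    "commands: simulate detect extract classify stats run-all", sep = "\n")
  if (length(args) == 0L || args[1] %in% c("-h", "--help")) {
    message(usage); return(invisible(1L))
  }
  cmd <- args[1]
  ok_cmds <- c("simulate", "detect", "extract", "classify", "stats", "run-all")
  if (!cmd %in% ok_cmds) { message("unknown command: ", cmd, "\n", usage)
                           return(invisible(1L)) }
  res <- tryCatch({
    flags <- .parse_flags(args[-1])
    bad <- setdiff(names(flags),
                   c("config", "seed", "out", "system", "task", "classifier"))
    abort_if(length(bad) > 0, "unknown flag(s): %s", paste(bad, collapse = ", "))
    config <- if (!is.null(flags$config)) read_sim_config(flags$config)
              else sim_config()
    if (!is.null(flags$seed)) config$seed <- as.integer(flags$seed)
    out <- flags$out %||% "imugait_out"
    systems <- switch(flags$system %||% "both", both = c("imu", "walkway"),
                      imu = "imu", walkway = "walkway",
                      stop("unknown system: ", flags$system))
    tasks <- if (is.null(flags$task) || flags$task == "three-class") "three-class"
             else if (flags$task == "all") CLASSIFY_TASKS
             else { abort_if(!flags$task %in% CLASSIFY_TASKS,
                             "unknown task: %s", flags$task); flags$task }
    classifiers <- if (is.null(flags$classifier)) "rf"
                   else if (flags$classifier == "all") c("svm", "rf", "xgb")
                   else { abort_if(!flags$classifier %in% c("svm", "rf", "xgb"),
                                   "unknown classifier: %s", flags$classifier)
                          flags$classifier }

    if (cmd %in% c("simulate", "run-all")) {
      cohort <- simulate_cohort(config)
      write_cohort(cohort, file.path(out, "simulated"))
      write_manifest("simulate", file.path(out, "manifest_simulate.json"),
                     seed = config$seed, config = config,
                     outputs = file.path(out, "simulated"))
    }
    if (cmd %in% c("detect", "extract", "classify", "stats", "run-all")) {
      sim_dir <- file.path(out, "simulated")
      abort_if(!dir.exists(sim_dir),
               "missing input: %s (run `simulate` first)", sim_dir)
      cohort <- read_cohort(sim_dir)
    }
    if (cmd %in% c("detect", "run-all")) {
      det <- lapply(cohort$trials, function(tr) {
        seg <- segment_trial(tr$imu)
        cbind(data.frame(subject_id = tr$subject_id, condition = tr$condition,
                         trial_index = tr$trial_index), seg$events)
      })
      write_events_table(data.table::rbindlist(det),
                         file.path(out, "detected_events.csv"))
      write_manifest("detect", file.path(out, "manifest_detect.json"),
                     seed = config$seed, config = config,
                     outputs = file.path(out, "detected_events.csv"))
    }
    if (cmd %in% c("extract", "classify", "stats", "run-all")) {
      feats <- lapply(stats::setNames(systems, systems),
                      function(s) cohort_parameter_table(cohort, s))
      if (cmd %in% c("extract", "run-all")) {
        for (s in systems)
          data.table::fwrite(feats[[s]],
                             file.path(out, sprintf("parameters_%s.csv", s)))
        write_manifest("extract", file.path(out, "manifest_extract.json"),
                       seed = config$seed, config = config,
                       outputs = file.path(out, sprintf("parameters_%s.csv", systems)))
      }
    }
    if (cmd %in% c("classify", "run-all")) {
      summaries <- list()
      for (s in systems) for (task in tasks) for (cl in classifiers)
        summaries[[length(summaries) + 1L]] <-
          run_task(feats[[s]], task, s, classifier_spec(cl),
                   seed = config$seed)$summary
      data.table::fwrite(do.call(rbind, summaries),
                         file.path(out, "classification_summary.csv"))
      write_manifest("classify", file.path(out, "manifest_classify.json"),
                     seed = config$seed, config = config,
                     outputs = file.path(out, "classification_summary.csv"))
    }
    if (cmd %in% c("stats", "run-all")) {
      for (s in systems)
        data.table::fwrite(descriptive_report(feats[[s]], pairwise = TRUE),
                           file.path(out, sprintf("descriptives_%s.csv", s)))
      write_manifest("stats", file.path(out, "manifest_stats.json"),
                     seed = config$seed, config = config,
                     outputs = file.path(out, sprintf("descriptives_%s.csv", systems)))
    }
    0L
  }, error = function(e) { message("error: ", conditionMessage(e))
                           message(usage); 1L })
  invisible(res)
}
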