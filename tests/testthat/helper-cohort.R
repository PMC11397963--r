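# Shared simulated fixtures, built once per test session.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (is.null(.fixture_env[[key]])) .fixture_env[[key]] <- builder()
  .fixture_env[[key]]
}

# full-size study cohort: 10 subjects x 10 trials x 3 conditions, seed 1
ref_cohort <- function() memo("ref_cohort", function()
  simulate_cohort(sim_config(n_subjects = 10, n_trials = 10, seed = 1)))

ref_features <- function(system) memo(paste0("feat_", system), function()
  cohort_parameter_table(ref_cohort(), system))

# small cohort for structural tests: 5 subjects x 2 trials
small_cohort <- function() memo("small_cohort", function()
  simulate_cohort(sim_config(n_subjects = 5, n_trials = 2, seed = 42)))

small_trial <- function() small_cohort()$trials[[1]]

# event-matching F1 against ground truth at a sample tolerance
event_f1 <- function(trial, truth, tol_samples = 2, fs = 50) {
  tol <- tol_samples / fs + 1e-9
  seg <- segment_trial(trial)
  tp <- 0L; np <- 0L; nt <- nrow(truth$events)
  for (l in c("L", "R")) for (ty in c("HS", "TO")) {
    det <- seg$events$time[seg$events$leg == l & seg$events$type == ty]
    tru <- truth$events$time[truth$events$leg == l & truth$events$type == ty]
    np <- np + length(det)
    used <- rep(FALSE, length(tru))
    for (t in det) {
      j <- which(!used & abs(tru - t) <= tol)
      if (length(j)) { used[j[1]] <- TRUE; tp <- tp + 1L }
    }
  }
  c(tp = tp, detected = np, truth = nt)
}
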