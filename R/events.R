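# Gait event detection from shank sagittal angular velocity.
#
# The shank angular-velocity trace shows, per gait cycle, one dominant
# positive peak in mid-swing flanked by two sharp negative troughs: the
# trough immediately before the peak marks toe-off (TO), the trough
# immediately after marks the next heel strike (HS). Peaks and troughs are
# located with a topographic-prominence peak finder (prominence threshold in
# deg/s, minimum separation in samples).

#' Find prominent local maxima
#'
#' Local maxima with topographic prominence at or above `prominence`. The
#' prominence of a peak is its height minus the higher of the two lowest
#' points one must descend to on either side before reaching higher terrain
#' (or the signal edge). When two surviving peaks are closer than
#' `min_separation` samples, the higher one is kept (greedy, highest first).
#'
#' @param signal Numeric series (length >= 3).
#' @param prominence Minimum topographic prominence (> 0).
#' @param min_separation Minimum distance between kept peaks, in samples.
#' @return Sorted integer vector of peak sample indices (possibly empty).
#' @export
find_prominent_extrema <- function(signal, prominence = 20, min_separation = 20) {
  abort_if(length(signal) < 3L, "signal must have at least 3 samples")
  abort_if(!is.numeric(prominence) || prominence <= 0, "prominence must be > 0")
  abort_if(!is_count(min_separation), "min_separation must be >= 1")
  n <- length(signal)
  x <- as.numeric(signal)
  core <- 2:(n - 1L)
  is_peak <- x[core] > x[core - 1L] & x[core] > x[core + 1L]
  peaks <- core[is_peak]
  if (length(peaks) == 0L) return(integer(0))

  prom <- vapply(peaks, function(p) {
    h <- x[p]
    left <- if (p > 1L) x[seq_len(p - 1L)] else numeric(0)
    hi <- which(left >= h)
    lbase <- min(x[(if (length(hi)) max(hi) else 1L):p])
    right <- if (p < n) x[(p + 1L):n] else numeric(0)
    hi <- which(right >= h)
    rbase <- min(x[p:(if (length(hi)) p + min(hi) else n)])
    h - max(lbase, rbase)
  }, 0)
  peaks <- peaks[prom >= prominence]
  if (length(peaks) <= 1L) return(peaks)

  keep <- logical(length(peaks))
  ord <- order(x[peaks], decreasing = TRUE)
  for (i in ord) {
    if (!any(keep & abs(peaks - peaks[i]) < min_separation)) keep[i] <- TRUE
  }
  sort(peaks[keep])
}

#' Detect heel-strike and toe-off events for one leg
#'
#' Locates mid-swing positive peaks and negative troughs (prominent extrema
#' of the negated signal) on the leg's shank angular velocity; labels the
#' trough immediately before each mid-swing peak TO and the trough
#' immediately after it HS. Events within `edge_guard` seconds of the record
#' edges are dropped (their context is incomplete). The result is
#' time-sorted and strictly alternating within the leg.
#'
#' @param trial An `imu_trial`.
#' @param leg `"L"` or `"R"`.
#' @param prominence,min_separation Peak-finder settings (deg/s, samples).
#' @param edge_guard Edge exclusion zone in seconds.
#' @return data.frame with columns `leg`, `type`, `time`, `sample_index`.
#' @export
detect_events <- function(trial, leg = c("L", "R"), prominence = 20,
                          min_separation = 20, edge_guard = 0.25) {
  abort_if(!inherits(trial, "imu_trial"), "trial must be an imu_trial")
  leg <- match.arg(leg)
  ch <- paste0("angvel_shank_", leg)
  abort_if(!ch %in% names(trial$data), "missing channel %s", ch)
  v <- trial$data[[ch]]
  tt <- trial$data$time

  peaks <- find_prominent_extrema(v, prominence, min_separation)
  # mid-swing dominance: the forward-swing peak towers over any residual
  # stance-phase bump, so require a substantial fraction of the trial maximum
  peaks <- peaks[v[peaks] > 0.3 * max(v)]
  abort_if(length(peaks) < 2L, "insufficient gait cycles")
  troughs <- find_prominent_extrema(-v, prominence, min_separation)

  events <- list()
  for (p in peaks) {
    before <- troughs[troughs < p]
    after <- troughs[troughs > p]
    if (length(before))
      events[[length(events) + 1L]] <- c(type = "TO", idx = max(before))
    if (length(after))
      events[[length(events) + 1L]] <- c(type = "HS", idx = min(after))
  }
  abort_if(length(events) == 0L, "insufficient gait cycles")
  ev <- data.frame(type = vapply(events, `[[`, "", "type"),
                   sample_index = as.integer(vapply(events, `[[`, "", "idx")))
  # a trough claimed as both TO (for one peak) and HS (for another) means the
  # peak/trough topology is not gait-like
  dup <- ev$sample_index[duplicated(ev$sample_index)]
  abort_if(length(dup) > 0, "event alternation violated: ambiguous trough labelling")

  ev <- ev[order(ev$sample_index), , drop = FALSE]
  ev$time <- tt[ev$sample_index]
  ev$leg <- leg
  lo <- tt[1] + edge_guard; hi <- tt[length(tt)] - edge_guard
  ev <- ev[ev$time >= lo & ev$time <= hi, , drop = FALSE]
  abort_if(nrow(ev) < 2L, "insufficient gait cycles")
  abort_if(any(ev$type[-1] == ev$type[-nrow(ev)]),
           "event alternation violated")
  rownames(ev) <- NULL
  ev[, c("leg", "type", "time", "sample_index")]
}

#' Build gait cycles from an alternating event sequence
#'
#' One cycle per (HS, TO, next HS) triple; leading toe-offs and trailing
#' incomplete triples are dropped.
#'
#' @param events data.frame with columns `leg`, `type`, `time` (one leg).
#' @return data.frame with one row per cycle: `leg`, `t_hs1`, `t_to`,
#'   `t_hs2`, `stance_time`, `swing_time`, `cycle_time`.
#' @export
build_cycles <- function(events) {
  if (is.null(events) || nrow(events) == 0L)
    return(data.frame(leg = character(0), t_hs1 = numeric(0), t_to = numeric(0),
                      t_hs2 = numeric(0), stance_time = numeric(0),
                      swing_time = numeric(0), cycle_time = numeric(0)))
  abort_if(length(unique(events$leg)) > 1L, "build_cycles expects one leg at a time")
  ev <- events[order(events$time), , drop = FALSE]
  abort_if(any(ev$type[-1] == ev$type[-nrow(ev)]),
           "events must alternate HS/TO")
  out <- list()
  i <- 1L
  while (i + 2L <= nrow(ev)) {
    if (ev$type[i] == "HS" && ev$type[i + 1L] == "TO" && ev$type[i + 2L] == "HS") {
      out[[length(out) + 1L]] <- data.frame(
        leg = ev$leg[i], t_hs1 = ev$time[i], t_to = ev$time[i + 1L],
        t_hs2 = ev$time[i + 2L])
      i <- i + 2L
    } else i <- i + 1L
  }
  if (length(out) == 0L) return(build_cycles(events[0, , drop = FALSE]))
  cyc <- do.call(rbind, out)
  cyc$stance_time <- cyc$t_to - cyc$t_hs1
  cyc$swing_time <- cyc$t_hs2 - cyc$t_to
  cyc$cycle_time <- cyc$t_hs2 - cyc$t_hs1
  abort_if(any(cyc$stance_time <= 0) || any(cyc$swing_time <= 0),
           "degenerate cycle")
  cyc
}

#' Pair left and right gait cycles by temporal overlap
#'
#' Each cycle is matched to the opposite-leg cycle with which it shares the
#' largest time overlap, provided the overlap exceeds half the shorter
#' cycle's duration; every cycle is used at most once and unmatched cycles
#' are discarded. Matching is greedy on descending overlap, which makes the
#' result symmetric in the two legs.
#'
#' @param left,right Cycle data.frames from [build_cycles()].
#' @return data.frame with one row per pair: left and right cycle fields
#'   (suffixed `_L`, `_R`) and the shared `overlap` in seconds.
#' @export
pair_cycles <- function(left, right) {
  empty <- data.frame(t_hs1_L = numeric(0), t_to_L = numeric(0),
                      t_hs2_L = numeric(0), stance_time_L = numeric(0),
                      swing_time_L = numeric(0), cycle_time_L = numeric(0),
                      t_hs1_R = numeric(0), t_to_R = numeric(0),
                      t_hs2_R = numeric(0), stance_time_R = numeric(0),
                      swing_time_R = numeric(0), cycle_time_R = numeric(0),
                      overlap = numeric(0))
  if (is.null(left) || is.null(right) || nrow(left) == 0L || nrow(right) == 0L)
    return(empty)
  cand <- expand.grid(i = seq_len(nrow(left)), j = seq_len(nrow(right)))
  cand$overlap <- pmax(0, pmin(left$t_hs2[cand$i], right$t_hs2[cand$j]) -
                            pmax(left$t_hs1[cand$i], right$t_hs1[cand$j]))
  cand$thresh <- 0.5 * pmin(left$cycle_time[cand$i], right$cycle_time[cand$j])
  cand <- cand[cand$overlap > cand$thresh, , drop = FALSE]
  if (nrow(cand) == 0L) return(empty)
  cand <- cand[order(-cand$overlap, cand$i, cand$j), , drop = FALSE]
  used_l <- logical(nrow(left)); used_r <- logical(nrow(right))
  rows <- list()
  for (k in seq_len(nrow(cand))) {
    i <- cand$i[k]; j <- cand$j[k]
    if (used_l[i] || used_r[j]) next
    used_l[i] <- TRUE; used_r[j] <- TRUE
    l <- left[i, c("t_hs1", "t_to", "t_hs2", "stance_time", "swing_time",
                   "cycle_time")]
    r <- right[j, c("t_hs1", "t_to", "t_hs2", "stance_time", "swing_time",
                    "cycle_time")]
    names(l) <- paste0(names(l), "_L"); names(r) <- paste0(names(r), "_R")
    rows[[length(rows) + 1L]] <- cbind(l, r, overlap = cand$overlap[k])
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$t_hs1_L), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Detect events and build cycle pairs for a whole trial
#'
#' @param trial An `imu_trial`.
#' @param ... Passed to [detect_events()].
#' @return A list with `events` (both legs), `cycles` (per-leg list), and
#'   `pairs` (from [pair_cycles()]).
#' @export
segment_trial <- function(trial, ...) {
  ev_l <- detect_events(trial, "L", ...)
  ev_r <- detect_events(trial, "R", ...)
  cyc_l <- build_cycles(ev_l)
  cyc_r <- build_cycles(ev_r)
  list(events = rbind(ev_l, ev_r),
       cycles = list(L = cyc_l, R = cyc_r),
       pairs = pair_cycles(cyc_l, cyc_r))
}
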