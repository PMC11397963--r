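# Independent brute-force oracles used to cross-check the implementation.

# Topographic prominence peak finder, written independently of the package:
# plain O(n^2) scans, explicit sorting for the minimum-distance rule.
oracle_prominent_peaks <- function(x, prominence, min_distance) {
  n <- length(x)
  peaks <- integer(0)
  for (i in 2:(n - 1)) if (x[i] > x[i - 1] && x[i] > x[i + 1]) peaks <- c(peaks, i)
  if (!length(peaks)) return(integer(0))
  prom <- numeric(length(peaks))
  for (pi in seq_along(peaks)) {
    p <- peaks[pi]; h <- x[p]
    lmin <- h
    j <- p - 1
    while (j >= 1 && x[j] < h) { lmin <- min(lmin, x[j]); j <- j - 1 }
    if (j < 1) lmin <- min(x[1:p])
    rmin <- h
    j <- p + 1
    while (j <= n && x[j] < h) { rmin <- min(rmin, x[j]); j <- j + 1 }
    if (j > n) rmin <- min(x[p:n])
    prom[pi] <- h - max(lmin, rmin)
  }
  keep <- peaks[prom >= prominence]
  if (length(keep) <= 1) return(keep)
  ord <- keep[order(x[keep], decreasing = TRUE)]
  sel <- integer(0)
  for (p in ord) if (!length(sel) || all(abs(sel - p) >= min_distance))
    sel <- c(sel, p)
  sort(sel)
}

# Friedman statistic by explicit row-wise ranking.
oracle_friedman <- function(m) {
  n <- nrow(m); k <- ncol(m)
  rank_sums <- numeric(k)
  for (i in seq_len(n)) rank_sums <- rank_sums + rank(m[i, ])
  12 / (n * k * (k + 1)) * sum(rank_sums^2) - 3 * n * (k + 1)
}

# Exact two-sided signed-rank p-value by explicit enumeration of sign vectors.
oracle_wilcoxon_exact <- function(x, y) {
  d <- (x - y)[x != y]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- min(sum(r[d > 0]), sum(r[d < 0]))
  count <- 0L
  for (mask in 0:(2^n - 1)) {
    signs <- bitwAnd(bitwShiftR(mask, 0:(n - 1)), 1L) == 1L
    if (sum(r[signs]) <= w_obs + 1e-9) count <- count + 1L
  }
  min(1, 2 * count / 2^n)
}

# Single/double support via explicit interval arithmetic on a footfall table.
oracle_support_times <- function(ff, i) {
  # stride of footfall i (same side at i + 2)
  t1 <- ff$t_contact[i]; stance_end <- ff$t_off[i]
  opp <- ff[ff$side != ff$side[i], , drop = FALSE]
  grid <- seq(t1, stance_end, by = 1e-4)
  on_opp <- vapply(grid, function(t)
    any(opp$t_contact <= t & t < opp$t_off), TRUE)
  double <- mean(on_opp) * (stance_end - t1)
  single <- (1 - mean(on_opp)) * (stance_end - t1)
  c(single = single, double = double)
}

# A trial whose left and right channels (and cycles) are exactly mirrored;
# used for the symmetry-ratio identities.
mirrored_trial <- function() {
  fs <- 50
  tt <- seq(0, 5, by = 1 / fs)
  shank <- 30 * sin(2 * pi * tt / 1.2) + 5 * sin(4 * pi * tt / 1.2)
  thigh <- shank + 25 * pmax(sin(2 * pi * tt / 1.2 - 0.5), 0)
  data <- data.frame(time = tt,
                     angle_thigh_L = thigh, angle_thigh_R = thigh,
                     angle_shank_L = shank, angle_shank_R = shank,
                     angvel_shank_L = c(0, diff(shank)) * fs,
                     angvel_shank_R = c(0, diff(shank)) * fs)
  new_imu_trial("S01", "normal", 1L, fs, data)
}
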