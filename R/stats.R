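# Nonparametric repeated-measures post-analysis.
#
# The statistical unit is the subject: each subject's cycles are averaged per
# condition, giving an n-subjects x k-conditions matrix per parameter. The
# Friedman test (chi-square approximation, df = k - 1) screens for any
# condition effect; paired Wilcoxon signed-rank tests with Bonferroni
# correction localise it.

#' Subject-by-condition mean matrices
#'
#' @param features Parameter table from [cohort_parameter_table()] (keys +
#'   parameter columns).
#' @param parameters Which parameter columns to aggregate (default: all).
#' @return Named list of `condition_matrix` objects, one per parameter:
#'   subjects x conditions matrices of subject means with attributes
#'   `parameter`.
#' @export
subject_condition_means <- function(features, parameters = NULL) {
  keys <- c("subject_id", "condition", "trial_index", "cycle_index")
  cols <- parameters %||% setdiff(names(features), keys)
  abort_if(!all(cols %in% names(features)), "unknown parameter(s): %s",
           paste(setdiff(cols, names(features)), collapse = ", "))
  subjects <- sort(unique(features$subject_id))
  conds <- intersect(c("normal", "knee", "ankle"), unique(features$condition))
  out <- lapply(cols, function(p) {
    m <- matrix(NA_real_, length(subjects), length(conds),
                dimnames = list(subjects, conds))
    for (s in subjects) for (cc in conds) {
      v <- features[[p]][features$subject_id == s & features$condition == cc]
      abort_if(length(v) == 0L,
               "no observations for subject %s in condition %s", s, cc)
      m[s, cc] <- mean(v)
    }
    structure(m, parameter = p, class = c("condition_matrix", "matrix", "array"))
  })
  stats::setNames(out, cols)
}

#' Friedman test statistic
#'
#' Ranks each subject's k condition values (average ranks on ties) and
#' computes S = 12 / (n k (k + 1)) * sum_j R_j^2 - 3 n (k + 1), where R_j is
#' the rank sum of condition j over the n subjects.
#'
#' @param m Numeric subjects x conditions matrix (n >= 2, k >= 2, no NA).
#' @return The statistic (>= 0; at most n (k - 1) under perfect consistency).
#' @export
friedman_statistic <- function(m) {
  m <- as.matrix(m)
  abort_if(anyNA(m), "condition matrix has missing cells")
  n <- nrow(m); k <- ncol(m)
  abort_if(n < 2L || k < 2L, "need at least 2 subjects and 2 conditions")
  ranks <- t(apply(m, 1, rank))
  rj <- colSums(ranks)
  12 / (n * k * (k + 1)) * sum(rj^2) - 3 * n * (k + 1)
}

#' Upper-tail chi-square probability
#'
#' Survival function of the chi-square distribution, used for the Friedman
#' test p-value with df = k - 1. For df = 2 it equals exp(-x / 2).
#'
#' @param x Statistic (>= 0).
#' @param df Degrees of freedom (>= 1).
#' @return P(X >= x).
#' @export
chi_square_sf <- function(x, df) {
  abort_if(any(x < 0), "x must be >= 0")
  abort_if(any(df < 1), "df must be >= 1")
  stats::pchisq(x, df, lower.tail = FALSE)
}

#' Friedman test for one condition matrix
#'
#' @param m Subjects x conditions matrix.
#' @return A `stat_result` list: `test`, `statistic`, `p_value`, `df`.
#' @export
friedman_test <- function(m) {
  s <- friedman_statistic(m)
  df <- ncol(m) - 1L
  structure(list(test = "friedman", statistic = s,
                 p_value = chi_square_sf(s, df), df = df,
                 comparison = paste(colnames(m), collapse = "/")),
            class = "stat_result")
}

#' Paired Wilcoxon signed-rank test
#'
#' Differences of exactly zero are dropped; |differences| are ranked with
#' average ranks on ties; W is the smaller of the positive- and
#' negative-rank sums. For n <= 12 retained pairs the two-sided p-value is
#' exact, by enumeration of all 2^n sign assignments of the realised ranks;
#' beyond that a normal approximation with tie correction and continuity
#' correction is used.
#'
#' @param x,y Paired numeric samples of equal length.
#' @param exact_max Largest n for which enumeration is used.
#' @return A `stat_result` list: `test`, `statistic` (W), `p_value`, `n`
#'   (retained pairs), `method`.
#' @export
wilcoxon_signed_rank <- function(x, y, exact_max = 12L) {
  abort_if(length(x) != length(y), "x and y must have equal length")
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  abort_if(n == 0L, "degenerate pairs: all differences are zero")
  abort_if(n < 5L, "need at least 5 nonzero differences")
  r <- rank(abs(d))
  w_pos <- sum(r[d > 0])
  w_neg <- sum(r[d < 0])
  w <- min(w_pos, w_neg)
  if (n <= exact_max) {
    # null distribution of the positive-rank sum over all sign assignments
    sums <- 0
    for (ri in r) sums <- as.vector(outer(sums, c(0, ri), `+`))
    p <- min(1, 2 * mean(sums <= w + 1e-9))
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (w - mu + 0.5) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(z))
    method <- "normal-approximation"
  }
  structure(list(test = "wilcoxon", statistic = w, p_value = p, n = n,
                 method = method),
            class = "stat_result")
}

#' Bonferroni-corrected significance decisions
#'
#' Divides the 0.05 and 0.01 levels by the number of comparisons and flags
#' each p-value at both corrected thresholds.
#'
#' @param p_values Numeric vector of p-values.
#' @param m Number of comparisons (default: number of p-values).
#' @return data.frame with `p_value`, `significant_05`, `significant_01`, and
#'   the corrected thresholds as attributes.
#' @export
bonferroni <- function(p_values, m = length(p_values)) {
  abort_if(!is_count(m), "m must be a positive integer")
  out <- data.frame(p_value = p_values,
                    significant_05 = p_values < 0.05 / m,
                    significant_01 = p_values < 0.01 / m)
  attr(out, "threshold_05") <- 0.05 / m
  attr(out, "threshold_01") <- 0.01 / m
  out
}

#' Pairwise Wilcoxon tests across conditions with Bonferroni correction
#'
#' @param m Subjects x conditions matrix.
#' @return data.frame with one row per condition pair: comparison label, W,
#'   raw p, and Bonferroni decisions at 0.05 and 0.01 (m = number of pairs).
#' @export
pairwise_wilcoxon <- function(m) {
  m <- as.matrix(m)
  cmb <- utils::combn(colnames(m), 2)
  rows <- lapply(seq_len(ncol(cmb)), function(i) {
    a <- cmb[1, i]; b <- cmb[2, i]
    res <- wilcoxon_signed_rank(m[, a], m[, b])
    data.frame(comparison = paste(a, b, sep = " vs "),
               statistic = res$statistic, p_value = res$p_value, n = res$n)
  })
  out <- do.call(rbind, rows)
  dec <- bonferroni(out$p_value, m = nrow(out))
  out$significant_05 <- dec$significant_05
  out$significant_01 <- dec$significant_01
  out
}

#' Descriptive statistics and Friedman screen per parameter
#'
#' Reproduces the structure of a repeated-measures descriptive table: one row
#' per parameter (and side, where sided), mean and SD per condition across
#' subject means, the Friedman statistic and its chi-square p-value, and
#' optionally the pairwise Wilcoxon decisions.
#'
#' @param features Parameter table from [cohort_parameter_table()].
#' @param pairwise Add Bonferroni-corrected pairwise Wilcoxon columns.
#' @param digits Rounding: statistics 1 d.p., p-values 4 d.p., means/SDs
#'   2 d.p.; set to `NULL` for unrounded output.
#' @return data.frame with one row per parameter.
#' @export
descriptive_report <- function(features, pairwise = FALSE, digits = TRUE) {
  mats <- subject_condition_means(features)
  rows <- lapply(mats, function(m) {
    fr <- friedman_test(m)
    row <- list(parameter = attr(m, "parameter"))
    for (cc in colnames(m)) {
      mu <- mean(m[, cc]); sdv <- stats::sd(m[, cc])
      if (isTRUE(digits)) { mu <- round(mu, 2); sdv <- round(sdv, 2) }
      row[[paste0(cc, "_mean")]] <- mu
      row[[paste0(cc, "_sd")]] <- sdv
    }
    row$friedman_statistic <- if (isTRUE(digits)) round(fr$statistic, 1) else fr$statistic
    row$p_value <- if (isTRUE(digits)) round(fr$p_value, 4) else fr$p_value
    if (pairwise) {
      pw <- pairwise_wilcoxon(m)
      for (i in seq_len(nrow(pw))) {
        lab <- gsub(" vs ", "_vs_", pw$comparison[i])
        row[[paste0(lab, "_p")]] <-
          if (isTRUE(digits)) round(pw$p_value[i], 4) else pw$p_value[i]
        row[[paste0(lab, "_sig05")]] <- pw$significant_05[i]
        row[[paste0(lab, "_sig01")]] <- pw$significant_01[i]
      }
    }
    as.data.frame(row)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
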