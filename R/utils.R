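# Internal helpers: argument checks, deterministic RNG streams.

`%||%` <- function(a, b) if (is.null(a)) b else a

abort_if <- function(cond, msg, ...) {
  if (isTRUE(cond)) stop(sprintf(msg, ...), call. = FALSE)
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 1 && x == round(x)
}

#' Derive a deterministic RNG stream seed from a root seed and labels
#'
#' Maps `(root_seed, label...)` to a seed in `[0, 2^31 - 2]` via a polynomial
#' rolling hash of the concatenated labels. Streams for distinct
#' (subject, condition, trial) labels are effectively independent, so adding
#' trials or subjects to a cohort never perturbs existing draws.
#'
#' @param root_seed Integer root seed for the whole run.
#' @param ... Character or numeric labels identifying the stream.
#' @return A single integer usable with [set.seed()].
#' @keywords internal
#' @export
stream_seed <- function(root_seed, ...) {
  abort_if(!is.numeric(root_seed) || length(root_seed) != 1L || !is.finite(root_seed),
           "root_seed must be a single finite number")
  key <- paste(c(format(root_seed), vapply(list(...), as.character, "")),
               collapse = "\r")
  m <- 2147483647  # 2^31 - 1, prime
  h <- root_seed %% m
  for (code in utf8ToInt(key)) h <- (h * 131 + code) %% m
  as.integer(h)
}

with_stream <- function(root_seed, ..., expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(stream_seed(root_seed, ...))
  expr
}

# total time (overlap measure) of intersection between interval [a1,a2] and a
# set of intervals given as two vectors
interval_overlap <- function(a1, a2, starts, ends) {
  if (length(starts) == 0L) return(0)
  sum(pmax(0, pmin(a2, ends) - pmax(a1, starts)))
}
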