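# Internal helpers: seeding, argument checking.

#' Evaluate code under a fixed RNG seed, restoring the caller's RNG state
#' @noRd
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

#' Derive a named substream seed from a base seed
#'
#' Every stochastic stage (trajectory, schedule, plant, carrier, network
#' initialization, ...) draws from its own deterministic substream so any
#' stage can be re-run in isolation.  The hash stays below 2^31 - 1.
#'
#' @param seed base integer seed.
#' @param name substream label, e.g. `"trajectory"`.
#' @param index optional replicate index within the substream.
#' @return an integer seed.
#' @export
substream_seed <- function(seed, name, index = 0L) {
  stopifnot(is.character(name), length(name) == 1L)
  m <- 2147483647  # 2^31 - 1
  h <- as.numeric(seed) %% m
  for (ch in utf8ToInt(name)) h <- (h * 131 + ch) %% m
  h <- (h * 131 + as.numeric(index) + 1) %% m
  as.integer(h %% (m - 1) + 1)
}

stop_invalid <- function(...) stop(sprintf(...), call. = FALSE)

check_scalar <- function(x, name, positive = FALSE, nonnegative = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_invalid("'%s' must be a finite numeric scalar", name)
  if (positive && x <= 0) stop_invalid("'%s' must be > 0", name)
  if (nonnegative && x < 0) stop_invalid("'%s' must be >= 0", name)
  invisible(x)
}
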