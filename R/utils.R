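# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate code under a temporary RNG seed
#'
#' Runs `code` with the global random number generator seeded to `seed`, then
#' restores the caller's RNG state, so library calls never perturb a user's
#' random stream.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  code
}

# Deterministic per-record / per-stage sub-seed derived from one master seed.
# Kept strictly below 2^31 - 1 so it is always a valid R integer seed.
substream_seed <- function(seed, index, salt = 0L) {
  s <- (as.numeric(seed) %% 1e6) * 7919 + as.numeric(index) * 104729 +
    as.numeric(salt) * 15485863 + 12345
  as.integer(s %% 2147483647)
}

assert_probability <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    stop(sprintf("`%s` must be a single probability in [0, 1]", name),
         call. = FALSE)
  }
  invisible(x)
}

assert_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min ||
      x != round(x)) {
    stop(sprintf("`%s` must be a single integer >= %d", name, min),
         call. = FALSE)
  }
  invisible(as.integer(x))
}

# Round half away from zero to `digits` decimals (report display convention;
# base round() rounds half to even).
round_half_up <- function(x, digits = 3) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
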