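# Internal helpers: seed management and logging.

#' Derive a reproducible sub-seed from a master seed
#'
#' Deterministic mixing keeps every derived seed a valid 32-bit integer so
#' that independent pipeline stages (bagging, Monte-Carlo, splitting) can run
#' on their own streams without sharing global RNG state.
#'
#' @param seed master seed (integer).
#' @param index stream index (integer >= 0).
#' @return an integer in [0, 2^31 - 2].
#' @keywords internal
derive_seed <- function(seed, index = 0L) {
  # 2147483647 = 2^31 - 1 (Mersenne prime); multiplicative mixing keeps
  # streams for consecutive indices far apart.
  s <- (as.double(seed) %% 2147483647) + 1
  x <- (s * 48271 + as.double(index) * 16807 + 11) %% 2147483647
  x <- (x * 69621) %% 2147483647
  as.integer(x)
}

# Evaluate `code` under `seed`, restoring the caller's RNG state afterwards.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
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
  force(code)
}

# Logging to stderr with a level prefix; quiet unless option set.
ddg_log <- function(..., level = "INFO") {
  if (isTRUE(getOption("ddgsampler.quiet", FALSE))) return(invisible(NULL))
  message(sprintf("[%s] %s", level, paste0(...)))
}

# Numeric formatting that survives a write/read round trip exactly.
format_ddg <- function(x) {
  vapply(x, function(v) {
    if (is.na(v)) "NA"
    else if (v == round(v) && abs(v) < 1e15) sprintf("%.1f", v)
    else sprintf("%.17g", v)
  }, character(1))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
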