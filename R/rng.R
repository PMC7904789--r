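#' Named random-number substreams
#'
#' Every stochastic component of the package draws from a named substream
#' derived from a single experiment seed, so that e.g. regenerating the
#' stimuli of an experiment never perturbs the internal-noise draws of the
#' integrator. The substream seed is a deterministic (counter-based) hash of
#' the master seed, the role name, and an optional counter.
#'
#' @param seed master integer seed.
#' @param role character tag naming the noise role, e.g. `"stimulus"`,
#'   `"internal"`, `"connectivity"`, `"init"`, `"external"`, `"tiebreak"`.
#' @param counter optional non-negative integer distinguishing successive
#'   draws in the same role (substream index).
#' @return an integer seed in `[0, 2^31 - 2]`.
#' @export
substream_seed <- function(seed, role, counter = 0L) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(role))
  # 32-bit multiplicative hash, kept in double arithmetic below 2^31
  h <- (abs(seed) %% 2147483647)
  for (ch in utf8ToInt(role)) h <- (h * 69069 + ch) %% 2147483647
  h <- (h * 69069 + (counter %% 2147483647)) %% 2147483647
  as.integer(h)
}

#' Evaluate code under a named substream, restoring the caller's RNG state
#'
#' @param seed,role,counter passed to [substream_seed()].
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_substream <- function(seed, role, code, counter = 0L) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(substream_seed(seed, role, counter))
  force(code)
}
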