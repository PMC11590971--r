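#' @keywords internal
"_PACKAGE"

#' @importFrom stats fft sd median var aov t.test wilcox.test shapiro.test
#'   friedman.test p.adjust pt rnorm runif rbinom rexp approx complete.cases
#' @importFrom utils head tail write.csv read.csv
NULL

#' Deterministic named substreams from one master seed
#'
#' All randomness in a session bundle flows from a single master seed;
#' each stream (eeg, gaze, trace, ...) derives its own 31-bit seed from
#' the master seed and a name, so any part of a bundle can be regenerated
#' on its own.
#'
#' @param seed master seed (integer-like).
#' @param name substream name.
#' @return A 31-bit integer seed.
#' @export
substream_seed <- function(seed, name) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  codes <- utf8ToInt(as.character(name))
  h <- as.double(seed) %% 2147483647
  for (c in codes) h <- (h * 31 + c) %% 2147483647
  as.integer(h)
}

#' Evaluate an expression under a temporary RNG seed
#'
#' Sets the seed, runs `code`, and restores the caller's RNG state.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return The value of `code`.
#' @export
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

assert_that <- function(ok, msg) if (!isTRUE(ok)) stop(msg, call. = FALSE)
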