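#' @keywords internal
"_PACKAGE"

#' @importFrom stats rnorm runif rbinom quantile setNames chisq.test
#' @importFrom utils head tail write.csv
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

abort_br <- function(msg, ...) stop(sprintf(msg, ...), call. = FALSE)

#' Derive a per-stage seed from a global seed
#'
#' Every stochastic stage of the pipeline draws its own seed from the single
#' global seed so that stages can be rerun in isolation and still reproduce
#' the end-to-end run. The derivation hashes the stage name onto the global
#' seed and reduces modulo 2^31 - 1 so the result is always a valid R integer
#' seed.
#'
#' @param seed integer global seed.
#' @param stage character stage name (e.g. `"simulate"`, `"train"`).
#' @return an integer seed.
#' @export
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.character(stage))
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((abs(seed) %% 65536L) * 32749 + h * 97) %% 2147483647L
}

with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

round1 <- function(x) round(x, 1)
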