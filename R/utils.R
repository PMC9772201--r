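#' @useDynLib memchoice, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm rbinom runif rlnorm qnorm pnorm dnorm qbeta sd cor
#'   median quantile integrate optim nlminb binomial glm coef vcov logLik
#'   anova pchisq pt t.test cor.test setNames complete.cases plogis qlogis
#'   glm.fit
#'   density approx aggregate ks.test ecdf rcauchy
#' @importFrom utils read.csv write.csv head
NULL

#' Inverse-logit and logit
#'
#' Numerically safe logistic transforms used throughout the generators and
#' fitters.
#'
#' @param x numeric vector.
#' @param p probabilities in (0, 1).
#' @return numeric vector.
#' @keywords internal
inv_logit <- function(x) plogis(x)

#' @rdname inv_logit
#' @keywords internal
logit <- function(p) qlogis(p)

#' Derive a named substream seed from a root seed
#'
#' All randomness in the package flows from one root seed through named
#' substreams (items, recognition, ratings, choices, ...), so any stage can be
#' regenerated in isolation. The derivation is a small deterministic string
#' hash folded into the root seed; results stay inside the 32-bit integer
#' range `set.seed()` accepts.
#'
#' @param seed integer root seed.
#' @param stream character substream name.
#' @return an integer seed.
#' @export
#' @examples
#' substream_seed(1, "items")
#' substream_seed(1, "ratings")
substream_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.character(stream))
  h <- 2166136261
  for (ch in utf8ToInt(stream)) {
    h <- (bitwXor(h %% 2^31, ch) * 16777619) %% 2147483629
  }
  as.integer((abs(seed) + h) %% 2147483629)
}

#' FNV-1a hash of a configuration object
#'
#' Used to stamp a provenance hash into every on-disk output so a stage can be
#' matched back to the exact configuration that produced it.
#'
#' @param x any R object (deparsed before hashing).
#' @return character hex digest.
#' @export
config_hash <- function(x) {
  s <- paste(deparse(x), collapse = "\n")
  h <- 2166136261
  for (ch in utf8ToInt(s)) {
    h <- (bitwXor(h %% 2^31, ch) * 16777619) %% 2^32
  }
  sprintf("%08x", as.integer(h %% 2^31))
}

clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_data <- function(...) stop(..., call. = FALSE)
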