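#' Derive a child seed for a named random stream
#'
#' A single master seed is expanded into independent, named child streams
#' (schedule / neural / behavior / opto ...) so that each generator can be
#' re-run on its own without disturbing the others.
#'
#' @param seed Master seed (single integer).
#' @param stream Character name of the stream.
#' @return An integer seed, deterministic in `(seed, stream)` and < 2^31.
#' @export
childSeed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stream))
  h <- 0
  for (ch in utf8ToInt(stream)) h <- (h * 131 + ch) %% 2147480009
  as.integer((abs(seed) * 48271 + h) %% 2147480009)
}

# shared internal: stop with a classed configuration error
.configError <- function(...) {
  stop(errorCondition(paste0(...), class = c("crossmodalConfigError", "error")))
}

.dataError <- function(...) {
  stop(errorCondition(paste0(...), class = c("crossmodalDataError", "error")))
}

#' Standard error of the mean
#' @param x Numeric vector; `NA` removed.
#' @return `sd(x)/sqrt(n)`.
#' @export
sem <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 2L) return(NA_real_)
  stats::sd(x) / sqrt(length(x))
}
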