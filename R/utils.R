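# Internal helpers shared across modules.

#' Derive a deterministic sub-seed for a named random stream
#'
#' One global seed plus a stream name map to an integer below 2^31. Each
#' generated variable draws from its own stream, so adding a variable to the
#' generator never perturbs the draws of earlier variables.
#'
#' @param seed integer global seed.
#' @param stream character stream label.
#' @return an integer seed.
#' @keywords internal
substream_seed <- function(seed, stream) {
  h <- 0
  for (ch in utf8ToInt(stream)) h <- (h * 31 + ch) %% 1000003
  as.integer((abs(as.numeric(seed)) %% 1048576) * 1009 + h)
}

with_stream <- function(seed, stream, fn) {
  set.seed(substream_seed(seed, stream))
  fn()
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_ <- function(...) stop(..., call. = FALSE)

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# Wald-style 95% interval on the link scale.
ci95 <- function(beta, se) c(beta - 1.96 * se, beta + 1.96 * se)

wald_p <- function(beta, se) 2 * stats::pnorm(-abs(beta / se))
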