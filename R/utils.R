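#' Derive a stage- or iteration-specific seed from a master seed
#'
#' Deterministic fan-out of one master seed into independent sub-seeds, so
#' each pipeline stage (or Boruta iteration) is reproducible in isolation.
#' The label is hashed with a small polynomial rolling hash and combined
#' with the master seed modulo a prime below 2^31.
#'
#' @param seed integer master seed.
#' @param label character label of the consuming stage.
#' @return A single integer seed in `[1, 2147483562]`.
#' @export
derive_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(label))
  m <- 2147483563
  h <- 0
  for (code in utf8ToInt(label)) h <- (h * 31 + code) %% m
  as.integer((abs(seed) %% m + h * 7919) %% m + 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# shared check: positive scalar count
.check_count <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 1 || x != round(x))
    stop(sprintf("invalid configuration: '%s' must be a positive integer", name),
         call. = FALSE)
  as.integer(x)
}
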