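#' Derive a reproducible child seed from a base seed and integer tags
#'
#' All randomness in the simulator flows from a single run seed; per-round and
#' per-client seeds are derived deterministically so that client updates are
#' order-independent (parallel semantics) and runs are exactly reproducible.
#' The result is always a valid 32-bit R seed.
#'
#' @param seed integer base seed.
#' @param ... integer tags (e.g. round index, client id).
#' @return an integer in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, ...) {
  parts <- c(seed, ...)
  acc <- 0
  for (p in parts) {
    acc <- (acc * 69069 + as.numeric(p) + 12345) %% 2147483647
  }
  as.integer(acc)
}

sigmoid <- function(x) 1 / (1 + exp(-x))

relu <- function(x) {
  x[x < 0] <- 0
  x
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_if_not_count <- function(x, name, min = 1L) {
  if (length(x) != 1L || is.na(x) || x < min || x != as.integer(x)) {
    stop(sprintf("`%s` must be a single integer >= %d", name, min), call. = FALSE)
  }
  invisible(as.integer(x))
}
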