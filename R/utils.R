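# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a child RNG seed from a root seed and an integer salt
#'
#' All stochastic stages (generation, fold shuffling, SMOTE, Shapley
#' sampling) draw their seeds through this function so that one root seed
#' reproduces an entire experiment while stages stay decoupled.
#'
#' @param seed integer root seed.
#' @param salt integer stage/event index.
#' @return an integer in `[0, 2^31 - 2]`.
#' @keywords internal
derive_seed <- function(seed, salt) {
  # multiplicative hash kept in double space; 2147483647 = 2^31 - 1 (prime)
  s <- (abs(as.numeric(seed)) %% 2147483647)
  v <- (s * 48271 + as.numeric(salt) * 104729 + 12345) %% 2147483647
  as.integer(v)
}

abort_usage <- function(msg, class = "fallwin_usage_error") {
  rlang::abort(msg, class = c(class, "fallwin_error"))
}

abort_data <- function(msg, class = "fallwin_data_error") {
  rlang::abort(msg, class = c(class, "fallwin_error"))
}

assert_finite_numeric <- function(x, what) {
  if (!is.numeric(x) || anyNA(x) || any(!is.finite(x))) {
    abort_usage(sprintf("%s must be finite numeric values", what))
  }
  invisible(x)
}
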