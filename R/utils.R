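# internal numeric + misc helpers

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' @keywords internal
abort_nerlstm <- function(msg, class) {
  rlang::abort(msg, class = c(class, "nerlstm_error"))
}

# derive an independent sub-seed from a master seed; kept below 2^31
derive_seed <- function(seed, k) {
  as.integer((as.double(seed) * 48271 + k * 10007) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
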