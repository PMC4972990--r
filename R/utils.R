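# Classed conditions so the CLI can map failure modes to exit codes.

abort_input <- function(msg, ...) {
  rlang::abort(msg, class = "lexiscreen_input_error", ...)
}

abort_validation <- function(msg, ...) {
  rlang::abort(msg, class = "lexiscreen_validation_error", ...)
}

abort_usage <- function(msg, ...) {
  rlang::abort(msg, class = "lexiscreen_usage_error", ...)
}

#' @keywords internal
split_multi <- function(x, sep = "|") {
  out <- strsplit(x, sep, fixed = TRUE)
  lapply(out, function(v) v[nzchar(v)])
}

join_multi <- function(x, sep = "|") {
  vapply(x, paste, character(1), collapse = sep)
}

# Derive a reproducible 31-bit sub-seed from a master seed and a stream label,
# so each fixture component draws from its own stream.
derive_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483629L)
}
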