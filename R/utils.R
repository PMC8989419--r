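#' @keywords internal
"_PACKAGE"

# Lightweight logging: messages are collected so pipeline runs can dump a
# per-run log, and emitted as R conditions so tests can capture them.
.prmepi_log <- new.env(parent = emptyenv())
.prmepi_log$lines <- character()

log_note <- function(...) {
  msg <- paste0(...)
  .prmepi_log$lines <- c(.prmepi_log$lines, msg)
  message(msg)
  invisible(msg)
}

#' Retrieve and optionally clear the session log
#'
#' The package records data-quality events (dropped strata, excluded
#' subjects, separation, non-convergence) in a session log so that batch
#' runs remain auditable.
#'
#' @param clear logical; reset the log after reading.
#' @return Character vector of log lines.
#' @export
get_log <- function(clear = FALSE) {
  out <- .prmepi_log$lines
  if (clear) .prmepi_log$lines <- character()
  out
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

# Draw a derived RNG seed (kept below 2^31) from a base seed and a label,
# so independent simulation streams are reproducible from one user seed.
derive_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647L)
}
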