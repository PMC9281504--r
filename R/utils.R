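# condition helpers ---------------------------------------------------------

abort_pushrim <- function(message, class, ...) {
  rlang::abort(message, class = c(paste0("pushrim_error_", class), "pushrim_error"), ...)
}

warn_qc <- function(message, ...) {
  rlang::warn(message, class = c("pushrim_warning_qc", "pushrim_warning"), ...)
}

check_number <- function(x, name, min = -Inf, max = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < min || x > max) {
    abort_pushrim(
      sprintf("`%s` must be a single finite number in [%s, %s]", name, min, max),
      class = "value"
    )
  }
  invisible(x)
}

check_choice <- function(x, name, choices) {
  if (!is.character(x) || length(x) != 1L || !(x %in% choices)) {
    abort_pushrim(
      sprintf("`%s` must be one of: %s", name, paste(choices, collapse = ", ")),
      class = "value"
    )
  }
  x
}

is_odd <- function(n) n %% 2L == 1L
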