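# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

is_count <- function(x) {
  length(x) == 1L && is.numeric(x) && is.finite(x) && x >= 1 && x == round(x)
}

stop_histocyto <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "histocyto_error")))
}

warn_histocyto <- function(msg, class) {
  warning(warningCondition(msg, class = c(class, "histocyto_warning")))
}
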