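#' @keywords internal
"_PACKAGE"

# Classed errors so callers can distinguish validation failures from
# numerical ones.
abort_cellmech <- function(msg, class, call. = FALSE) {
  stop(errorCondition(msg, class = c(class, "cellmech_error")))
}

stop_invalid_parameter <- function(msg) abort_cellmech(msg, "cellmech_invalid_parameter")
stop_domain <- function(msg) abort_cellmech(msg, "cellmech_domain_error")

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

check_positive_scalar <- function(x, name) {
  if (!is_number(x) || x <= 0)
    stop_invalid_parameter(sprintf("`%s` must be a single positive finite number", name))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
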