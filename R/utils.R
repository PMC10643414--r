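`%||%` <- function(a, b) if (is.null(a)) b else a

check_positive <- function(x, name) {
  if (any(!is.finite(x)) || any(x <= 0))
    stop(sprintf("`%s` must be finite and > 0", name), call. = FALSE)
  invisible(x)
}
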