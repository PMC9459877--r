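# classed error helper: all package errors carry class "gaitsva_error" plus a
# specific subclass so callers/tests can match on condition class
gait_stop <- function(msg, class, call = sys.call(-1)) {
  stop(structure(
    class = c(class, "gaitsva_error", "error", "condition"),
    list(message = msg, call = call)
  ))
}

stopifnot_scalar_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
    gait_stop(sprintf("`%s` must be a single positive finite number", name),
              "gaitsva_invalid_parameter")
  invisible(x)
}
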