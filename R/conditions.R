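# Classed conditions so callers (and tests) can distinguish failure modes.
# Classes: input, shape, validation, parse, config, degenerate, io, invariant.

cdkd_error <- function(message, class, call = sys.call(-1)) {
  stop(structure(
    class = c(paste0("cdkd_", class, "_error"), "cdkd_error",
              "error", "condition"),
    list(message = message, call = call)
  ))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
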