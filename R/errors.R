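# Classed conditions so callers (and tests) can distinguish failure modes.
nsph_error <- function(class, msg, call = sys.call(-1)) {
  stop(structure(
    class = c(class, "nsphere_error", "error", "condition"),
    list(message = msg, call = call)
  ))
}

# Positive scalar / vector guards used across constructors.
is_finite_num <- function(x) is.numeric(x) && all(is.finite(x))
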