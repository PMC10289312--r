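# Classed conditions so callers (and the pipeline) can react per failure mode.
wv_error <- function(class, message, ...) {
  structure(class = c(class, "wheelvault_error", "error", "condition"),
            list(message = message, call = sys.call(-1), ...))
}

wv_stop <- function(class, message, ...) stop(wv_error(class, message, ...))
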