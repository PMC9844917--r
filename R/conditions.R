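# Classed conditions so callers can distinguish codec failures programmatically.
# All inherit from "ddqr_error".

stop_ddqr <- function(subclass, message, call = sys.call(-1), ...) {
  cnd <- structure(
    class = c(subclass, "ddqr_error", "error", "condition"),
    list(message = message, call = call, ...)
  )
  stop(cnd)
}
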