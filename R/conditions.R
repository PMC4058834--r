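# Classed error conditions so callers can distinguish failure modes.

abort_fmrf <- function(message, class, call = sys.call(-1)) {
  stop(structure(
    class = c(class, "fmrf_error", "error", "condition"),
    list(message = message, call = call)
  ))
}

# Re-raise any error from `expr` with the pipeline stage name prepended,
# keeping the original condition classes.
with_stage <- function(stage, expr) {
  withCallingHandlers(expr, error = function(e) {
    if (inherits(e, "fmrf_stage_error")) return(invisible(NULL))
    stop(structure(
      class = unique(c("fmrf_stage_error", class(e))),
      list(message = sprintf("[stage %s] %s", stage, conditionMessage(e)),
           call = conditionCall(e), stage = stage)
    ))
  })
}
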