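# Classed conditions so callers (and the CLI) can distinguish bad input
# from numerical failure (e.g. a reducible operator).

stop_input <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c("lmm_input_error", "lmm_error")))
}

stop_numerical <- function(fmt, ..., data = NULL) {
  cond <- errorCondition(sprintf(fmt, ...),
                         class = c("lmm_numerical_error", "lmm_error"))
  cond$data <- data
  stop(cond)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
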