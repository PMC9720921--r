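# Structured conditions so callers (and the CLI) can map failures to exit
# codes without string matching. All package errors inherit "hii_error".

stop_hii <- function(class, message, ..., call = sys.call(-1)) {
  data <- list(...)
  cond <- structure(
    class = c(class, "hii_error", "error", "condition"),
    c(list(message = message, call = call), data)
  )
  stop(cond)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
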