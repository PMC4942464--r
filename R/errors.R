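# Classed conditions used across the package. The CLI dispatcher maps
# p2e_data_error/p2e_format_error to exit code 2 and p2e_fit_error/
# p2e_collinear_error to exit code 3.

p2e_stop <- function(msg, class, ...) {
  stop(structure(
    class = c(class, "p2e_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

abort_data <- function(msg, ...) p2e_stop(msg, "p2e_data_error", ...)
abort_format <- function(msg, ...) p2e_stop(msg, "p2e_format_error", ...)
abort_fit <- function(msg, ...) p2e_stop(msg, "p2e_fit_error", ...)
abort_collinear <- function(msg, ...) p2e_stop(msg, "p2e_collinear_error", ...)
abort_param <- function(msg, ...) p2e_stop(msg, "p2e_param_error", ...)
abort_catalog <- function(msg, ...) p2e_stop(msg, "p2e_catalog_error", ...)
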