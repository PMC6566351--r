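#' @keywords internal
ctmr_abort <- function(message, class) {
  stop(structure(
    class = c(class, "ctmrsyn_error", "error", "condition"),
    list(message = message, call = sys.call(-1))
  ))
}

config_error <- function(msg) ctmr_abort(msg, "ctmrsyn_config_error")
data_error <- function(msg) ctmr_abort(msg, "ctmrsyn_data_error")
shape_error <- function(msg) ctmr_abort(msg, "ctmrsyn_shape_error")
numeric_error <- function(msg) ctmr_abort(msg, "ctmrsyn_numeric_error")
validation_error <- function(msg) ctmr_abort(msg, "ctmrsyn_validation_error")
version_error <- function(msg) ctmr_abort(msg, "ctmrsyn_version_error")

# Exit codes for the command-line entry point: configuration, data (incl.
# shape/validation), numeric; anything else exits 1.
error_exit_code <- function(cond) {
  if (inherits(cond, "ctmrsyn_config_error")) return(2L)
  if (inherits(cond, c("ctmrsyn_data_error", "ctmrsyn_shape_error",
                       "ctmrsyn_validation_error", "ctmrsyn_version_error"))) {
    return(3L)
  }
  if (inherits(cond, "ctmrsyn_numeric_error")) return(4L)
  1L
}
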