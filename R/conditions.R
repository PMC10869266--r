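# Typed error conditions. Every validation failure raised by the package
# carries a subclass of "riborunoff_error" so callers (and the test suite)
# can distinguish geometry problems from format, design or fit problems.

stop_riborunoff <- function(class, message, ...) {
  rlang::abort(message, class = c(class, "riborunoff_error"), ...)
}

stop_geometry     <- function(msg, ...) stop_riborunoff("geometry_error", msg, ...)
stop_format       <- function(msg, ...) stop_riborunoff("format_error", msg, ...)
stop_parameter    <- function(msg, ...) stop_riborunoff("parameter_error", msg, ...)
stop_idempotence  <- function(msg, ...) stop_riborunoff("idempotence_error", msg, ...)
stop_peak         <- function(msg, ...) stop_riborunoff("peak_not_found_error", msg, ...)
stop_segmentation <- function(msg, ...) stop_riborunoff("segmentation_error", msg, ...)
stop_division     <- function(msg, ...) stop_riborunoff("division_error", msg, ...)
stop_fit          <- function(msg, ...) stop_riborunoff("fit_error", msg, ...)
stop_design       <- function(msg, ...) stop_riborunoff("design_error", msg, ...)
stop_normalization <- function(msg, ...) stop_riborunoff("normalization_error", msg, ...)
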