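#' @title Condition classes
#' @description Internal helpers that raise classed conditions so callers (and
#'   the CLI exit-code mapping) can distinguish failure modes. All conditions
#'   inherit from `nutristock_error`.
#' @name nutristock-conditions
#' @keywords internal
NULL

ns_error <- function(class, message, ...) {
  stop(structure(
    class = c(class, "nutristock_error", "error", "condition"),
    list(message = message, call = sys.call(-1), ...)
  ))
}

io_error          <- function(msg, ...) ns_error("nutristock_io_error", msg, ...)
schema_error      <- function(msg, ...) ns_error("nutristock_schema_error", msg, ...)
value_error       <- function(msg, ...) ns_error(c("nutristock_value_error", "nutristock_schema_error"), msg, ...)
completeness_error<- function(msg, ...) ns_error(c("nutristock_completeness_error", "nutristock_schema_error"), msg, ...)
reference_error   <- function(msg, ...) ns_error(c("nutristock_reference_error", "nutristock_schema_error"), msg, ...)
config_error      <- function(msg, ...) ns_error("nutristock_config_error", msg, ...)
profile_error     <- function(msg, ...) ns_error(c("nutristock_profile_error", "nutristock_config_error"), msg, ...)
planning_error    <- function(msg, ...) ns_error("nutristock_planning_error", msg, ...)
consistency_error <- function(msg, ...) ns_error("nutristock_consistency_error", msg, ...)
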