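# Structured error conditions shared by all modules.

om_error <- function(class, message, ...) {
  stop(structure(
    class = c(class, "om_error", "error", "condition"),
    list(message = message, call = sys.call(-1), ...)
  ))
}

#' @name orthomount-errors
#' @title Error conditions
#' @description
#' All user-facing failures signal classed conditions so callers can react
#' programmatically:
#' \describe{
#'   \item{`degenerate_geometry`}{implausible landmark configuration: the
#'     nasal-rest offset exceeds the Pi--Ns distance, a vertical occlusal
#'     plane, collinear occlusal landmarks, or a hinge axis at/below the
#'     occlusal plane.}
#'   \item{`missing_landmark`}{a mandatory landmark is absent.}
#'   \item{`unknown_pivot`}{a named pivot does not exist on the jaw.}
#'   \item{`pivot_mismatch`}{pre/post jaws carry different pivot name sets.}
#'   \item{`missing_stage`}{a splint scenario requires a jaw stage that was
#'     never planned.}
#'   \item{`format_error`}{malformed STL or landmark file.}
#'   \item{`config_error`}{unknown or invalid configuration key.}
#' }
#' Hard errors are the default policy; a few operations take a `permissive`
#' flag that converts an exact degenerate limit into a limit-case return.
NULL

degenerate_geometry <- function(message, ...) om_error("degenerate_geometry", message, ...)
missing_landmark    <- function(message, ...) om_error("missing_landmark", message, ...)
unknown_pivot       <- function(message, ...) om_error("unknown_pivot", message, ...)
pivot_mismatch      <- function(message, ...) om_error("pivot_mismatch", message, ...)
missing_stage       <- function(message, ...) om_error("missing_stage", message, ...)
format_error        <- function(message, ...) om_error("format_error", message, ...)
config_error        <- function(message, ...) om_error("config_error", message, ...)
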