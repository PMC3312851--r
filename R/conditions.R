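# Classed error conditions so callers can distinguish failure modes with
# tryCatch(..., aortapwv_segmentation_error = ...) etc.

pwv_abort <- function(class, message, ...) {
  stop(errorCondition(message, ...,
                      class = c(paste0("aortapwv_", class), "aortapwv_error")))
}

#' Test whether a condition is an aortapwv error of a given class
#'
#' @param cond A condition object.
#' @param class Short class name, e.g. `"no_upslope_error"`; `NULL` matches
#'   any package error.
#' @return Logical scalar.
#' @export
is_pwv_error <- function(cond, class = NULL) {
  if (!inherits(cond, "aortapwv_error")) return(FALSE)
  if (is.null(class)) return(TRUE)
  inherits(cond, paste0("aortapwv_", class))
}
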