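# internal helpers shared across modules

#' Round half away from zero
#'
#' Commercial ("half-up") rounding, as used for all displayed counts and
#' monetary values in the scenario grid. Base R's `round()` rounds half to
#' even, which does not reproduce published tables that were rounded
#' half-up.
#'
#' @param x numeric vector.
#' @param digits integer; decimal places to keep (may be negative).
#' @return numeric vector rounded half away from zero at `digits`.
#' @examples
#' round_half_up(0.5)        # 1, where round(0.5) is 0
#' round_half_up(2.345, 2)   # 2.35
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  # small guard absorbs binary representation error just below a half-way
  # point (e.g. x * p = 152.99999999 for a value that is exactly 153)
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

# classed condition so callers can distinguish failure modes
vd_stop <- function(class, msg, call = sys.call(-1)) {
  stop(structure(
    class = c(paste0("vdfort_", class), "vdfort_error", "error", "condition"),
    list(message = msg, call = call)
  ))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

vd_debug <- function(...) {
  if (isTRUE(getOption("vdfort.debug", FALSE))) {
    message("[vdfort] ", sprintf(...))
  }
}
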