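#' Convert a concentration to millimolar
#'
#' All internal computation in hcdkin is done in mM and seconds; user-facing
#' functions accept the units the bench uses (nM enzyme, uM substrates) and
#' convert at the boundary through this helper.
#'
#' @param x numeric vector of concentrations.
#' @param unit one of `"M"`, `"mM"`, `"uM"`, `"nM"`.
#' @return numeric vector in mM.
#' @export
#' @examples
#' as_mM(160, "uM")  # 0.16
as_mM <- function(x, unit = c("mM", "uM", "nM", "M")) {
  unit <- match.arg(unit)
  factor <- c(M = 1e3, mM = 1, uM = 1e-3, nM = 1e-6)[[unit]]
  x * factor
}

#' Convert a concentration from millimolar
#'
#' @param x numeric vector in mM.
#' @param unit target unit, one of `"M"`, `"mM"`, `"uM"`, `"nM"`.
#' @return numeric vector in `unit`.
#' @export
from_mM <- function(x, unit = c("mM", "uM", "nM", "M")) {
  unit <- match.arg(unit)
  factor <- c(M = 1e3, mM = 1, uM = 1e-3, nM = 1e-6)[[unit]]
  x / factor
}

stop_if_negative <- function(x, what) {
  if (any(!is.finite(x) & !is.infinite(x)) || any(x < 0, na.rm = TRUE))
    stop(sprintf("%s must be non-negative and finite", what), call. = FALSE)
  invisible(x)
}
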