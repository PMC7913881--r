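#' Extinction-coefficient table for the HcdE assay
#'
#' The assay follows the reaction spectrophotometrically: substrate-panel
#' activity at 340 nm with a composite per-substrate coefficient, and
#' kinetic characterization at 365 nm where only NADPH absorbs
#' (epsilon_365 = 3500 M^-1 cm^-1). The 340 nm values are the composite
#' reaction coefficients used as single-epsilon conversions, exactly as the
#' assay applies them. Pathlength defaults to 1 cm (cuvette).
#'
#' @param pathlength_cm optical pathlength, cm.
#' @param extra named list of additional entries, each
#'   `list(epsilon = <M^-1 cm^-1>, wavelength = <nm>)`.
#' @return object of class `extinction_table`.
#' @export
extinction_table <- function(pathlength_cm = 1, extra = list()) {
  if (pathlength_cm <= 0) stop("pathlength must be positive", call. = FALSE)
  entries <- list(
    `7-hydroxycoumarin`     = list(epsilon = 5580, wavelength = 340),
    `6-hydroxycoumarin`     = list(epsilon = 4780, wavelength = 340),
    `6-methylcoumarin`      = list(epsilon = 4440, wavelength = 340),
    `6,7-dihydroxycoumarin` = list(epsilon = 8500, wavelength = 340),
    coumarin                = list(epsilon = 3690, wavelength = 340),
    NADPH                   = list(epsilon = 3500, wavelength = 365)
  )
  entries[names(extra)] <- extra
  for (e in entries)
    if (e$epsilon <= 0) stop("epsilon must be positive", call. = FALSE)
  structure(list(entries = entries, pathlength = pathlength_cm),
            class = "extinction_table")
}

#' Convert an absorbance trace to concentration
#'
#' Beer-Lambert: c = A / (epsilon * l), returned in uM.
#'
#' @param trace data.frame with columns `time_s` and `absorbance`; an
#'   optional attribute or column `wavelength` is checked against the table
#'   entry when present.
#' @param table an [extinction_table()].
#' @param analyte name of the absorbing species, looked up in `table`.
#' @return data.frame with columns `time_s`, `conc_uM`.
#' @export
#' @examples
#' tr <- data.frame(time_s = 0:3, absorbance = 0.56)
#' absorbance_to_concentration(tr, extinction_table(), "NADPH")  # 160 uM
absorbance_to_concentration <- function(trace, table = extinction_table(),
                                        analyte) {
  stopifnot(inherits(table, "extinction_table"))
  entry <- table$entries[[analyte]]
  if (is.null(entry))
    stop("analyte '", analyte, "' not in extinction table", call. = FALSE)
  wl <- trace$wavelength %||% attr(trace, "wavelength")
  if (!is.null(wl) && any(wl != entry$wavelength))
    stop("trace wavelength does not match table entry for '", analyte, "'",
         call. = FALSE)
  if (any(!is.finite(trace$absorbance)))
    stop("absorbance must be finite", call. = FALSE)
  conc_M <- trace$absorbance / (entry$epsilon * table$pathlength)
  data.frame(time_s = trace$time_s, conc_uM = conc_M * 1e6)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Initial rate from a concentration trace
#'
#' Least-squares slope over the early window in which the analyte has
#' changed by at most `max_conversion` of its initial value; reported as a
#' positive velocity regardless of direction (depletion traces give the
#' depletion rate). Adding a constant baseline to the trace leaves the rate
#' unchanged.
#'
#' @param conc_trace data.frame with columns `time_s` and `conc_uM`.
#' @param max_conversion fractional-change cap defining the window.
#' @param min_points minimum points required in the window.
#' @return velocity, uM/s.
#' @export
initial_rate <- function(conc_trace, max_conversion = 0.05, min_points = 5) {
  if (max_conversion <= 0)
    stop("max_conversion must be > 0 (empty window)", call. = FALSE)
  c0 <- conc_trace$conc_uM[1]
  conv <- if (c0 != 0) abs(conc_trace$conc_uM - c0) / abs(c0) else
    rep(0, nrow(conc_trace))
  keep <- conv <= max_conversion
  if (sum(keep) < min_points)
    stop("trace has fewer than ", min_points,
         " points inside the initial-rate window", call. = FALSE)
  tt <- conc_trace$time_s[keep]; yy <- conc_trace$conc_uM[keep]
  if (stats::var(tt) == 0) stop("degenerate time grid", call. = FALSE)
  abs(stats::cov(tt, yy) / stats::var(tt))
}

#' Relative substrate activities
#'
#' Fold-below-reference for each substrate in a velocity panel: fold =
#' mean(v_ref) / mean(v_substrate), computed on replicate means. Substrates
#' with zero mean velocity are flagged as inactive (`fold = NA`).
#'
#' @param panel named list mapping substrate to a numeric vector of
#'   replicate velocities (any common unit).
#' @param reference name of the reference substrate.
#' @return data.frame with columns `substrate`, `mean_velocity`, `fold`,
#'   `active`; reference row has fold 1.
#' @export
relative_activity <- function(panel, reference = "7-hydroxycoumarin") {
  if (length(panel) == 0) stop("empty panel", call. = FALSE)
  if (!reference %in% names(panel))
    stop("reference substrate '", reference, "' missing from panel",
         call. = FALSE)
  means <- vapply(panel, mean, numeric(1))
  v_ref <- means[[reference]]
  if (v_ref <= 0) stop("reference substrate has no activity", call. = FALSE)
  active <- means > 0
  fold <- ifelse(active, v_ref / means, NA_real_)
  data.frame(substrate = names(panel), mean_velocity = unname(means),
             fold = unname(fold), active = unname(active),
             row.names = NULL)
}
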