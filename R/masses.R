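# Embedded atomic-mass table (IUPAC/CODATA). Columns: most-abundant-isotope
# mass number (nominal), monoisotopic mass (u), standard atomic weight.
ATOMIC_MASSES <- data.frame(
  element = c("C", "H", "N", "O", "S", "P", "Na", "K", "Cl"),
  nominal = c(12, 1, 14, 16, 32, 31, 23, 39, 35),
  monoisotopic = c(12, 1.0078250319, 14.0030740052, 15.9949146221,
                   31.97207069, 30.97376151, 22.98976928, 38.9637064864,
                   34.968852682),
  average = c(12.011, 1.008, 14.007, 15.999, 32.06, 30.973761998,
              22.98976928, 39.0983, 35.45),
  stringsAsFactors = FALSE
)

PROTON_MASS <- 1.007276

#' Parse a molecular formula
#'
#' Hill-notation element symbols with optional counts, e.g. `"C9H6O3"`.
#'
#' @param s formula string.
#' @return named integer vector, element -> count; round-trips through
#'   [format_formula()].
#' @export
#' @examples
#' parse_formula("C9H9NO5")
parse_formula <- function(s) {
  stopifnot(is.character(s), length(s) == 1, nzchar(s))
  m <- gregexpr("[A-Z][a-z]?[0-9]*", s)[[1]]
  tokens <- regmatches(s, list(m))[[1]]
  if (sum(attr(m, "match.length")) != nchar(s))
    stop("cannot parse formula '", s, "'", call. = FALSE)
  elems <- sub("[0-9]*$", "", tokens)
  counts <- as.integer(ifelse(grepl("[0-9]+$", tokens),
                              sub("^[A-Za-z]+", "", tokens), "1"))
  unknown <- setdiff(elems, ATOMIC_MASSES$element)
  if (length(unknown) > 0)
    stop("unknown element symbol(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  comp <- tapply(counts, factor(elems, levels = unique(elems)), sum)
  storage.mode(comp) <- "integer"
  c(comp)
}

#' @rdname parse_formula
#' @param comp named count vector as returned by `parse_formula`.
#' @export
format_formula <- function(comp) {
  paste0(names(comp), ifelse(comp == 1, "", comp), collapse = "")
}

formula_mass <- function(comp, kind = c("nominal", "monoisotopic",
                                        "average")) {
  kind <- match.arg(kind)
  i <- match(names(comp), ATOMIC_MASSES$element)
  if (anyNA(i))
    stop("unknown element symbol(s): ",
         paste(names(comp)[is.na(i)], collapse = ", "), call. = FALSE)
  sum(ATOMIC_MASSES[[kind]][i] * comp)
}

#' Molecular weight from a composition
#'
#' @param comp composition from [parse_formula()] (a formula string is also
#'   accepted).
#' @return average molecular weight, g/mol.
#' @export
molecular_weight <- function(comp) {
  if (is.character(comp)) comp <- parse_formula(comp)
  formula_mass(comp, "average")
}

#' Adduct m/z for a composition
#'
#' Nominal masses are sums of the mass numbers of the most abundant
#' isotopes, so `[M-H]-` and `[M+H]+` are the integer mass -/+ 1 (the values
#' an ESI instrument prints as "Da"). Monoisotopic adducts subtract/add the
#' proton mass 1.007276.
#'
#' @param comp composition from [parse_formula()] (or a formula string).
#' @param adduct `"[M-H]-"` or `"[M+H]+"`.
#' @param mass_kind `"nominal"` or `"monoisotopic"`.
#' @return m/z (z = 1).
#' @export
#' @examples
#' adduct_mz("C9H6O3", "[M-H]-")  # 161
adduct_mz <- function(comp, adduct = c("[M-H]-", "[M+H]+"),
                      mass_kind = c("nominal", "monoisotopic")) {
  adduct <- match.arg(adduct)
  mass_kind <- match.arg(mass_kind)
  if (is.character(comp)) comp <- parse_formula(comp)
  m <- formula_mass(comp, mass_kind)
  shift <- if (mass_kind == "nominal") 1 else PROTON_MASS
  if (adduct == "[M-H]-") m - shift else m + shift
}

#' Pathway compound registry
#'
#' The seven intermediates of the proposed 7-hydroxycoumarin catabolic
#' pathway in P. mandelii 7HK4, from the substrate through ring reduction
#' (HcdE), lactone hydrolysis, hydroxylation/ring cleavage down to succinic
#' acid, plus the pyridine side product formed from the ring-cleavage
#' intermediate and ammonium.
#'
#' @return data.frame: `name`, `formula`, `pathway_index` (NA for the side
#'   product).
#' @export
pathway_registry <- function() {
  data.frame(
    name = c("7-hydroxycoumarin",
             "7-hydroxy-3,4-dihydrocoumarin",
             "3-(2,4-dihydroxyphenyl)propionic acid",
             "3-(2,3,5-trihydroxyphenyl)propionic acid",
             "(2E,4E)-2,4-dihydroxy-6-oxonona-2,4-dienedioic acid",
             "(E)-2-hydroxy-4-oxopent-2-enoic acid",
             "succinic acid",
             "6-(2-carboxyethyl)-4-oxo-1,4-dihydropyridine-2-carboxylic acid"),
    formula = c("C9H6O3", "C9H8O3", "C9H10O4", "C9H10O5", "C9H10O7",
                "C5H6O4", "C4H6O4", "C9H9NO5"),
    pathway_index = c(1:7, NA),
    stringsAsFactors = FALSE
  )
}

#' Match observed ions to registry compounds
#'
#' Each observation is assigned every registry compound whose adduct m/z at
#' the observation's polarity lies within `tol`; observations matching
#' nothing are listed as unassigned.
#'
#' @param observed data.frame with columns `mz` and `polarity` (`"+"` or
#'   `"-"`).
#' @param registry compound data.frame with `name` and `formula` (default
#'   [pathway_registry()]).
#' @param tol match tolerance, Da (> 0).
#' @param mass_kind `"nominal"` or `"monoisotopic"`.
#' @return data.frame: one row per (observation, match), `compound` NA for
#'   unassigned observations.
#' @export
match_ions <- function(observed, registry = pathway_registry(), tol = 0.5,
                       mass_kind = "nominal") {
  stopifnot(tol > 0, all(observed$mz > 0),
            all(observed$polarity %in% c("+", "-")))
  rows <- lapply(seq_len(nrow(observed)), function(i) {
    pol <- observed$polarity[i]
    add <- if (pol == "-") "[M-H]-" else "[M+H]+"
    theo <- vapply(registry$formula, adduct_mz, numeric(1),
                   adduct = add, mass_kind = mass_kind)
    hit <- which(abs(theo - observed$mz[i]) <= tol)
    if (length(hit) == 0)
      return(data.frame(mz = observed$mz[i], polarity = pol,
                        compound = NA_character_, theoretical_mz = NA_real_))
    data.frame(mz = observed$mz[i], polarity = pol,
               compound = registry$name[hit],
               theoretical_mz = unname(theo[hit]))
  })
  do.call(rbind, rows)
}

#' Conversion-yield stoichiometry
#'
#' Theoretical product mass for a 1:1 molar conversion, using average
#' molecular weights as bench stoichiometry does, and the percent of
#' theoretical achieved by an actual isolated mass.
#'
#' @param mass_in_mg starting material, mg.
#' @param comp_in,comp_out compositions (or formula strings) of starting
#'   material and product.
#' @param actual_mg isolated product mass, mg (optional).
#' @return list: `theoretical_mg`, `percent_of_theoretical` (NA when
#'   `actual_mg` missing), and the two molecular weights.
#' @export
#' @examples
#' theoretical_yield(59, "C9H6O3", "C9H10O4", actual_mg = 50)
theoretical_yield <- function(mass_in_mg, comp_in, comp_out,
                              actual_mg = NA_real_) {
  if (mass_in_mg <= 0) stop("mass_in must be positive", call. = FALSE)
  if (!is.na(actual_mg) && actual_mg <= 0)
    stop("actual mass must be positive", call. = FALSE)
  mw_in <- molecular_weight(comp_in)
  mw_out <- molecular_weight(comp_out)
  theo <- mass_in_mg * mw_out / mw_in
  list(theoretical_mg = theo,
       percent_of_theoretical = if (is.na(actual_mg)) NA_real_ else
         100 * actual_mg / theo,
       mw_in = mw_in, mw_out = mw_out)
}
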