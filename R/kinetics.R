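#' Macroscopic kinetic parameters of the HcdE rate law
#'
#' Bundle of the parameters of the ping-pong bi-substrate rate law with
#' pseudo-competitive substrate inhibition that describes NADPH-dependent
#' reduction of 7-hydroxycoumarin (7HK) by HcdE:
#' \deqn{v = \frac{E_0\,k_{bim}\,k_{NADPH}\,A\,B}
#'            {k_{NADPH} A + k_{bim} B \left(K_{m,NADPH} + A + A B / K_i\right)}}
#' with A = [NADPH] and B = [7HK]. `k_bim` is the bimolecular specificity
#' constant of the oxidative half-reaction (k_7HK / Km_7HK), `k_nadph` the
#' rate constant of NADPH oxidation (the catalytic constant), `km_nadph` the
#' Michaelis constant for NADPH at saturating 7HK, and `k_i` the dissociation
#' constant of the dead-end complex formed when 7HK binds the enzyme-NADPH
#' charge-transfer complex. `k_i = Inf` is the explicit "no substrate
#' inhibition" sentinel.
#'
#' @param e_total_nM total enzyme concentration, nM.
#' @param k_bim bimolecular rate constant of 7HK reduction, mM^-1 s^-1.
#' @param k_nadph rate constant of NADPH oxidation, s^-1.
#' @param km_nadph_uM Michaelis constant for NADPH, uM.
#' @param k_i_mM substrate-inhibition dissociation constant, mM; `Inf`
#'   disables inhibition.
#' @return an object of class `kinetic_params` (a named list, internal units
#'   mM and seconds).
#' @export
#' @examples
#' p <- kinetic_params(99, 1490, 27, 20, 22)
#' rate_ping_pong(p, nadph_uM = 160, s7hk_uM = 60)
kinetic_params <- function(e_total_nM, k_bim, k_nadph, km_nadph_uM,
                           k_i_mM = Inf) {
  vals <- c(e_total_nM, k_bim, k_nadph, km_nadph_uM)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all kinetic parameters must be strictly positive and finite",
         call. = FALSE)
  if (is.na(k_i_mM) || k_i_mM <= 0)
    stop("k_i must be strictly positive (Inf for no inhibition)",
         call. = FALSE)
  structure(list(
    e_total  = as_mM(e_total_nM, "nM"),
    k_bim    = k_bim,
    k_nadph  = k_nadph,
    km_nadph = as_mM(km_nadph_uM, "uM"),
    k_i      = k_i_mM
  ), class = "kinetic_params")
}

#' @export
print.kinetic_params <- function(x, ...) {
  cat("HcdE kinetic parameters\n")
  cat(sprintf("  E_total  : %g nM\n", from_mM(x$e_total, "nM")))
  cat(sprintf("  k_bim    : %g mM^-1 s^-1\n", x$k_bim))
  cat(sprintf("  k_NADPH  : %g s^-1\n", x$k_nadph))
  cat(sprintf("  Km_NADPH : %g uM\n", from_mM(x$km_nadph, "uM")))
  cat(sprintf("  K_i      : %s mM\n",
              if (is.infinite(x$k_i)) "Inf (no inhibition)" else
                format(x$k_i)))
  invisible(x)
}

#' Ping-pong rate law with substrate inhibition
#'
#' Evaluates the steady-state initial velocity of the HcdE reaction at given
#' NADPH and 7-hydroxycoumarin concentrations. Vectorized over the two
#' concentrations (recycled to common length).
#'
#' @param params a [kinetic_params()] object.
#' @param nadph_uM NADPH concentration(s), uM.
#' @param s7hk_uM 7-hydroxycoumarin concentration(s), uM.
#' @return velocity in uM/s, same length as the recycled inputs. Zero exactly
#'   when either substrate is zero.
#' @export
rate_ping_pong <- function(params, nadph_uM, s7hk_uM) {
  stopifnot(inherits(params, "kinetic_params"))
  stop_if_negative(nadph_uM, "[NADPH]")
  stop_if_negative(s7hk_uM, "[7HK]")
  a <- as_mM(nadph_uM, "uM")
  b <- as_mM(s7hk_uM, "uM")
  n <- max(length(a), length(b))
  a <- rep_len(a, n); b <- rep_len(b, n)
  inhib <- if (is.infinite(params$k_i)) 0 else a * b / params$k_i
  num <- params$e_total * params$k_bim * params$k_nadph * a * b
  den <- params$k_nadph * a +
    params$k_bim * b * (params$km_nadph + a + inhib)
  v <- ifelse(a == 0 | b == 0, 0, num / den)
  from_mM(v, "uM")
}

#' Elementary rate constants of the HcdE mechanism
#'
#' The mechanism is two half-reactions plus a dead-end branch:
#' reductive, E0 + NADPH <-> E1 -> E2 (binding k1/k_m1, hydride transfer
#' k_nadph); oxidative, E2 + 7HK <-> E3 -> E0 + NADP+ + product (binding
#' k2/k_m2, reduction k_7hk); dead-end, E1 + 7HK <-> Ei (ka/kd). The
#' macroscopic parameters are combinations of these:
#' Km_NADPH = (k_m1 + k_nadph)/k1, k_bim = k_7hk / ((k_m2 + k_7hk)/k2),
#' K_i = kd/ka.
#'
#' @param k1,k_m1 NADPH binding on/off, mM^-1 s^-1 and s^-1.
#' @param k_nadph hydride-transfer rate constant, s^-1.
#' @param k2,k_m2 7HK binding on/off at E2, mM^-1 s^-1 and s^-1.
#' @param k_7hk reduction/release rate constant, s^-1.
#' @param ka,kd dead-end binding on/off at E1, mM^-1 s^-1 and s^-1.
#' @return an object of class `micro_rates`.
#' @export
micro_rates <- function(k1, k_m1, k_nadph, k2, k_m2, k_7hk, ka, kd) {
  r <- list(k1 = k1, k_m1 = k_m1, k_nadph = k_nadph, k2 = k2,
            k_m2 = k_m2, k_7hk = k_7hk, ka = ka, kd = kd)
  bad <- vapply(r, function(v) !is.finite(v) || v < 0, logical(1))
  if (any(bad))
    stop("elementary rate constants must be non-negative and finite",
         call. = FALSE)
  structure(r, class = "micro_rates")
}

#' Macroscopic parameters implied by elementary rate constants
#'
#' Applies the defining relations Km_NADPH = (k_m1 + k_nadph)/k1,
#' k_bim = k2 * k_7hk / (k_m2 + k_7hk), K_i = kd/ka exactly.
#'
#' @param micro a [micro_rates()] object.
#' @param e_total_nM total enzyme concentration, nM.
#' @return a [kinetic_params()] object.
#' @export
macro_from_micro <- function(micro, e_total_nM) {
  stopifnot(inherits(micro, "micro_rates"))
  km_nadph <- (micro$k_m1 + micro$k_nadph) / micro$k1          # mM
  k_bim <- micro$k2 * micro$k_7hk / (micro$k_m2 + micro$k_7hk) # mM^-1 s^-1
  k_i <- if (micro$ka == 0) Inf else micro$kd / micro$ka       # mM
  kinetic_params(e_total_nM, k_bim, micro$k_nadph,
                 from_mM(km_nadph, "uM"), k_i)
}

#' Elementary rate constants consistent with macroscopic parameters
#'
#' The macroscopic set identifies only three combinations of the eight
#' elementary constants; the remainder are fixed by documented free choices:
#' `commitment` = k_m1/k_nadph (how reversible NADPH binding is), `excess` =
#' k_7hk/k_nadph (how much faster the oxidative chemistry is than hydride
#' transfer), and the dead-end on-rate `ka`. The reverse 7HK binding rate is
#' set to k_m2 = k_7hk; any positive value preserves the round trip. The
#' closed-form rate law neglects a denominator term of relative size
#' k_nadph/k_7hk = 1/excess, so `excess = 100` keeps the approximation below
#' 1%; `excess <= 2` triggers a warning.
#'
#' @param params a [kinetic_params()] object.
#' @param commitment ratio k_m1/k_nadph, > 0 (default 4).
#' @param excess ratio k_7hk/k_nadph, > 0 (default 100).
#' @param ka dead-end on-rate, mM^-1 s^-1 (default 1); ignored when
#'   `params$k_i` is infinite (dead-end branch switched off).
#' @return a [micro_rates()] object; `macro_from_micro()` on the result
#'   reproduces `params` exactly.
#' @export
micro_from_macro <- function(params, commitment = 4, excess = 100, ka = 1) {
  stopifnot(inherits(params, "kinetic_params"))
  if (!is.finite(commitment) || commitment <= 0 ||
      !is.finite(excess) || excess <= 0 || !is.finite(ka) || ka <= 0)
    stop("commitment, excess and ka must be strictly positive", call. = FALSE)
  if (excess <= 2)
    warning("excess ratio k_7hk/k_nadph <= 2: the closed-form rate law ",
            "neglects a term of relative size 1/excess and degrades here")
  k_nadph <- params$k_nadph
  k_m1 <- commitment * k_nadph
  k1 <- (k_m1 + k_nadph) / params$km_nadph
  k_7hk <- excess * k_nadph
  k_m2 <- k_7hk
  k2 <- params$k_bim * (k_m2 + k_7hk) / k_7hk
  if (is.infinite(params$k_i)) {
    ka <- 0; kd <- 0
  } else {
    kd <- ka * params$k_i
  }
  micro_rates(k1, k_m1, k_nadph, k2, k_m2, k_7hk, ka, kd)
}

#' Read/write kinetic parameters as YAML
#'
#' Serialized as a mapping from field name to `{value, unit}` so files are
#' self-describing.
#'
#' @param params a [kinetic_params()] object.
#' @param path file path.
#' @return `params_to_yaml` returns `path` invisibly; `params_from_yaml`
#'   returns a [kinetic_params()] object.
#' @export
params_to_yaml <- function(params, path) {
  stopifnot(inherits(params, "kinetic_params"))
  obj <- list(
    e_total  = list(value = from_mM(params$e_total, "nM"), unit = "nM"),
    k_bim    = list(value = params$k_bim, unit = "mM^-1 s^-1"),
    k_nadph  = list(value = params$k_nadph, unit = "s^-1"),
    km_nadph = list(value = from_mM(params$km_nadph, "uM"), unit = "uM"),
    k_i      = list(value = if (is.infinite(params$k_i)) ".inf" else
      params$k_i, unit = "mM")
  )
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname params_to_yaml
#' @export
params_from_yaml <- function(path) {
  obj <- yaml::read_yaml(path)
  ki <- obj$k_i$value
  if (identical(ki, ".inf")) ki <- Inf
  kinetic_params(obj$e_total$value, obj$k_bim$value, obj$k_nadph$value,
                 obj$km_nadph$value, as.numeric(ki))
}
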