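# Reference parameter point used throughout: the HcdE estimates
# (k_bim 1490 mM^-1 s^-1, k_NADPH 27 s^-1, Km_NADPH 20 uM, K_i 22 mM)
# at the assay enzyme load of 99 nM.
ref_params <- function() kinetic_params(99, 1490, 27, 20, 22)

# Independent closed-form evaluation of the rate law used as the oracle for
# rate_ping_pong(): written directly from the algebra in plain arithmetic,
# all quantities in mM and seconds.
oracle_rate_uM_s <- function(e_nM, k_bim, k_nadph, km_uM, ki_mM,
                             nadph_uM, s7hk_uM) {
  e <- e_nM * 1e-6; a <- nadph_uM * 1e-3; b <- s7hk_uM * 1e-3
  km <- km_uM * 1e-3
  num <- e * k_bim * k_nadph * a * b
  den <- k_nadph * a + k_bim * b * (km + a + a * b / ki_mM)
  1e3 * num / den
}

# Full clamped-substrate steady state of the mechanism in closed form
# (King-Altman style balance solution), the independent oracle for the
# linear-solve implementation. Units mM, s.
oracle_full_ss_mM_s <- function(micro, a, b, e_tot) {
  km_a <- (micro$k_m1 + micro$k_nadph) / micro$k1
  k_bim <- micro$k2 * micro$k_7hk / (micro$k_m2 + micro$k_7hk)
  ki <- if (micro$ka == 0) Inf else micro$kd / micro$ka
  den <- km_a / a + 1 + b / ki + micro$k_nadph / (k_bim * b) +
    micro$k_nadph / micro$k_7hk
  micro$k_nadph * e_tot / den
}
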