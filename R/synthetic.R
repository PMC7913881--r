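#' Initial-velocity experimental design
#'
#' Mirrors the kinetic characterization design: NADPH spanning 5-200 uM and
#' 7-hydroxycoumarin spanning 5-150 uM, eight log-spaced levels each, in
#' triplicate at 99 nM enzyme. The extended variant appends a multi-mM 7HK
#' series (0.5-60 mM) — a reconstruction of the high-concentration
#' inhibition observations, required to make K_i (22 mM) identifiable from
#' a design whose routine range stops at 150 uM.
#'
#' @param nadph_uM,s7hk_uM substrate levels, uM.
#' @param replicates replicate count per cell.
#' @param e_total_nM enzyme concentration, nM.
#' @param cv proportional noise coefficient of variation.
#' @param floor_uM_s additive noise floor, uM/s.
#' @param extended append the multi-mM 7HK inhibition series?
#' @return list of class `velocity_design`.
#' @export
velocity_design <- function(nadph_uM = 10^seq(log10(5), log10(200),
                                              length.out = 8),
                            s7hk_uM = 10^seq(log10(5), log10(150),
                                             length.out = 8),
                            replicates = 3, e_total_nM = 99,
                            cv = 0.03, floor_uM_s = 0.005,
                            extended = FALSE) {
  if (extended)
    s7hk_uM <- c(s7hk_uM, c(500, 2000, 8000, 24000, 60000))
  stopifnot(all(nadph_uM > 0), all(s7hk_uM > 0), replicates >= 1,
            e_total_nM > 0, cv >= 0, floor_uM_s >= 0)
  structure(list(nadph_uM = nadph_uM, s7hk_uM = s7hk_uM,
                 replicates = replicates, e_total_nM = e_total_nM,
                 cv = cv, floor_uM_s = floor_uM_s, extended = extended),
            class = "velocity_design")
}

#' Generate a synthetic initial-velocity dataset
#'
#' Velocities are the rate law evaluated on the design grid with
#' proportional plus additive Gaussian noise:
#' v = v_true * (1 + cv * xi) + floor * zeta. Negative draws are truncated
#' at zero (count attached as attribute `n_truncated`). Deterministic given
#' `seed`; the caller's RNG state is untouched.
#'
#' @param design a [velocity_design()].
#' @param params generating [kinetic_params()]; its enzyme concentration is
#'   overridden by the design's `e_total_nM`.
#' @param seed integer seed.
#' @return velocity dataset data.frame (`nadph_uM`, `s7hk_uM`, `v_uM_per_s`,
#'   `replicate`) with attributes `provenance` (`"synthetic"`), `seed`,
#'   `n_truncated`, `design`.
#' @export
generate_velocity_dataset <- function(design, params, seed = 42) {
  stopifnot(inherits(design, "velocity_design"),
            inherits(params, "kinetic_params"))
  gen <- kinetic_params(design$e_total_nM, params$k_bim, params$k_nadph,
                        from_mM(params$km_nadph, "uM"), params$k_i)
  grid <- expand.grid(nadph_uM = design$nadph_uM,
                      s7hk_uM = design$s7hk_uM,
                      replicate = seq_len(design$replicates),
                      KEEP.OUT.ATTRS = FALSE)
  v_true <- rate_ping_pong(gen, grid$nadph_uM, grid$s7hk_uM)
  v <- with_seed(seed, {
    n <- nrow(grid)
    v_true * (1 + design$cv * stats::rnorm(n)) +
      design$floor_uM_s * stats::rnorm(n)
  })
  n_trunc <- sum(v < 0)
  v[v < 0] <- 0
  out <- data.frame(nadph_uM = grid$nadph_uM, s7hk_uM = grid$s7hk_uM,
                    v_uM_per_s = v, replicate = grid$replicate)
  attr(out, "provenance") <- "synthetic"
  attr(out, "seed") <- seed
  attr(out, "n_truncated") <- n_trunc
  attr(out, "design") <- design
  out
}

#' Generate synthetic NADPH-depletion absorbance traces
#'
#' Integrates the full mass-action mechanism from the generating
#' parameters (via [micro_from_macro()] defaults), maps the NADPH
#' concentration through Beer-Lambert at 365 nm, and adds Gaussian read
#' noise. Feeding the traces back through
#' [absorbance_to_concentration()] and [initial_rate()] recovers the
#' generating velocity within noise-consistent tolerance.
#'
#' @param params generating [kinetic_params()].
#' @param nadph_uM,s7hk_uM initial substrate loads, uM (defaults: the
#'   standard assay, 160 and 60).
#' @param t_grid time grid, seconds.
#' @param table an [extinction_table()].
#' @param noise_sd_AU absorbance read noise SD.
#' @param replicates number of traces.
#' @param seed integer seed.
#' @return list of data.frames (`time_s`, `absorbance`), each with
#'   attributes `wavelength`, `analyte`, `replicate`, `seed`.
#' @export
generate_absorbance_traces <- function(params, nadph_uM = 160,
                                       s7hk_uM = 60,
                                       t_grid = seq(0, 2, by = 0.05),
                                       table = extinction_table(),
                                       noise_sd_AU = 0.002,
                                       replicates = 3, seed = 42) {
  stopifnot(inherits(params, "kinetic_params"))
  entry <- table$entries[["NADPH"]]
  micro <- micro_from_macro(params)
  init <- mechanism_state(as_mM(nadph_uM, "uM"), as_mM(s7hk_uM, "uM"),
                          params$e_total)
  traj <- simulate_mechanism(micro, init, t_grid)
  a_clean <- traj$nadph * 1e-3 * entry$epsilon * table$pathlength  # mM -> M
  with_seed(seed, lapply(seq_len(replicates), function(r) {
    tr <- data.frame(
      time_s = traj$time,
      absorbance = a_clean + stats::rnorm(length(a_clean), 0, noise_sd_AU))
    attr(tr, "wavelength") <- entry$wavelength
    attr(tr, "analyte") <- "NADPH"
    attr(tr, "replicate") <- r
    attr(tr, "seed") <- seed
    tr
  }))
}

#' Default expression-scenario configuration
#'
#' Encodes the induction structure of the transcription experiment: the hcd
#' cluster genes induced ~1000-fold by 7-hydroxycoumarin and
#' 3-(2,4-dihydroxyphenyl)propionic acid and ~100-fold by 7-methylcoumarin;
#' the constitutive xenA38 reductase induced only 2-3-fold; xenA45 never
#' detected. Also carries the generating kinetic parameters and the
#' relative-activity panel (rates 1.6-, 2-, 3.4- and 17-fold below the
#' 7-hydroxycoumarin reference).
#'
#' @param ct_sd replicate Ct noise SD, cycles.
#' @param efficiency amplification factor per cycle.
#' @return list of class `scenario_config`.
#' @export
scenario_config <- function(ct_sd = 0.3, efficiency = 2) {
  hcd <- c("hcdA", "hcdB", "hcdC", "hcdR", "hp4", "hcdD", "hcdE")
  inductions <- rbind(
    expand.grid(gene = hcd, condition = c("7-hydroxycoumarin", "DHFP"),
                stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE),
    expand.grid(gene = hcd, condition = "7-methylcoumarin",
                stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE),
    data.frame(gene = c("xenA38", "xenA38"),
               condition = c("7-hydroxycoumarin", "6-hydroxycoumarin"))
  )
  inductions$fold <- c(rep(1000, length(hcd) * 2), rep(100, length(hcd)),
                       3, 2)
  structure(list(
    params = kinetic_params(99, 1490, 27, 20, 22),
    panel_folds = c(`7-hydroxycoumarin` = 1, `6,7-dihydroxycoumarin` = 1.6,
                    `6-hydroxycoumarin` = 2, `6-methylcoumarin` = 3.4,
                    coumarin = 17),
    inductions = inductions,
    genes = c(hcd, "xenA38"),
    undetected_genes = "xenA45",
    conditions = c("glucose", "7-hydroxycoumarin", "DHFP",
                   "7-methylcoumarin", "6-hydroxycoumarin"),
    ct_sd = ct_sd, efficiency = efficiency
  ), class = "scenario_config")
}

#' Generate a synthetic Ct table
#'
#' Per-gene baseline Ct values are drawn once; induced conditions shift the
#' Ct down by log(fold)/log(efficiency) cycles; every measurement
#' (reference included) gets independent Gaussian replicate noise. Genes in
#' `undetected_genes` are emitted with `NA` Ct throughout. Deterministic
#' given `seed`.
#'
#' @param config a [scenario_config()].
#' @param replicates replicate count.
#' @param seed integer seed.
#' @return long-format Ct data.frame: `gene`, `condition`, `replicate`,
#'   `ct`, including the 16S reference rows.
#' @export
generate_ct_table <- function(config = scenario_config(), replicates = 3,
                              seed = 42) {
  stopifnot(inherits(config, "scenario_config"))
  with_seed(seed, {
    genes <- config$genes
    base_ct <- stats::setNames(stats::runif(length(genes), 26, 32), genes)
    rows <- list()
    for (cond in config$conditions) {
      for (g in c(genes, config$undetected_genes, "16S")) {
        if (g %in% config$undetected_genes) {
          ct <- rep(NA_real_, replicates)
        } else {
          mu <- if (g == "16S") 12 else {
            f <- config$inductions$fold[config$inductions$gene == g &
                                          config$inductions$condition == cond]
            shift <- if (length(f) == 1)
              log(f) / log(config$efficiency) else 0
            base_ct[[g]] - shift
          }
          ct <- mu + stats::rnorm(replicates, 0, config$ct_sd)
        }
        rows[[length(rows) + 1]] <- data.frame(
          gene = g, condition = cond, replicate = seq_len(replicates),
          ct = ct)
      }
    }
    do.call(rbind, rows)
  })
}

#' Generate a synthetic relative-activity panel
#'
#' Replicate velocities at the standard assay condition (160 uM NADPH,
#' 60 uM substrate) for the coumarin panel, with each substrate's mean rate
#' the reference rate divided by its programmed fold and proportional
#' Gaussian noise on replicates.
#'
#' @param config a [scenario_config()].
#' @param replicates replicates per substrate.
#' @param cv proportional noise CV.
#' @param seed integer seed.
#' @return named list, substrate -> numeric replicate velocities (uM/s).
#' @export
generate_activity_panel <- function(config = scenario_config(),
                                    replicates = 3, cv = 0.03, seed = 42) {
  stopifnot(inherits(config, "scenario_config"))
  v_ref <- rate_ping_pong(config$params, 160, 60)
  with_seed(seed, {
    out <- lapply(config$panel_folds, function(f) {
      (v_ref / f) * (1 + cv * stats::rnorm(replicates))
    })
    names(out) <- names(config$panel_folds)
    out
  })
}
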