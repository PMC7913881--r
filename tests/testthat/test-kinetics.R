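test_that("rate law matches independent closed-form evaluation and is zero
          without substrate or enzyme", {
  p <- ref_params()
  # standard assay condition, frozen from the hand evaluation of the algebra
  expect_equal(rate_ping_pong(p, 160, 60), 1.869569, tolerance = 1e-6)
  expect_equal(rate_ping_pong(p, 160, 60),
               oracle_rate_uM_s(99, 1490, 27, 20, 22, 160, 60))
  # oracle agreement across a grid, including the no-inhibition sentinel
  grid <- expand.grid(a = c(5, 20, 80, 200), b = c(5, 30, 150, 2000))
  expect_equal(rate_ping_pong(p, grid$a, grid$b),
               oracle_rate_uM_s(99, 1490, 27, 20, 22, grid$a, grid$b))
  p_inf <- kinetic_params(99, 1490, 27, 20, Inf)
  expect_equal(rate_ping_pong(p_inf, grid$a, grid$b),
               oracle_rate_uM_s(99, 1490, 27, 20, Inf, grid$a, grid$b))
  expect_identical(rate_ping_pong(p, 0, 60), 0)
  expect_identical(rate_ping_pong(p, 160, 0), 0)
  expect_error(rate_ping_pong(p, -1, 60), "non-negative")
})

test_that("substrate inhibition perturbs the denominator exactly as the
          algebra says and is negligible below 150 uM", {
  p_fin <- ref_params()
  p_inf <- kinetic_params(99, 1490, 27, 20, Inf)
  a <- 160; b <- 150
  ratio <- rate_ping_pong(p_inf, a, b) / rate_ping_pong(p_fin, a, b)
  # v_inf/v_fin = den_fin/den_inf; inhibition enters only via A*B/K_i
  am <- a * 1e-3; bm <- b * 1e-3
  den_inf <- 27 * am + 1490 * bm * (0.020 + am)
  den_fin <- den_inf + 1490 * bm * am * bm / 22
  expect_equal(ratio, den_fin / den_inf, tolerance = 1e-12)
  expect_lt(abs(ratio - 1), 0.01)
})

test_that("rate law is increasing in NADPH, unimodal in 7HK, linear in
          enzyme, and unit-consistent", {
  p <- ref_params()
  a_grid <- 10^seq(0, 3, length.out = 40)
  v_a <- rate_ping_pong(p, a_grid, 60)
  expect_true(all(diff(v_a) > 0))
  b_grid <- 10^seq(0, 6, length.out = 200)  # 1 uM .. 1 M
  v_b <- rate_ping_pong(p, 100, b_grid)
  s <- sign(diff(v_b))
  expect_equal(sum(diff(s) != 0), 1)        # one rise-to-fall turn
  expect_lt(v_b[length(v_b)], 0.05 * max(v_b))
  # no inhibition -> monotone in B
  v_b_inf <- rate_ping_pong(kinetic_params(99, 1490, 27, 20, Inf),
                            100, b_grid)
  expect_true(all(diff(v_b_inf) > 0))
  # bimolecular regime: dv/dB -> E0 * k_bim at saturating A, tiny B
  slope <- rate_ping_pong(p, 1e6, 1e-4) / 1e-4            # uM/s per uM
  expect_equal(slope, 99e-6 * 1490, tolerance = 1e-3)
  # linear in enzyme
  p2 <- kinetic_params(198, 1490, 27, 20, 22)
  expect_equal(rate_ping_pong(p2, 160, 60), 2 * rate_ping_pong(p, 160, 60))
  # unit round trip on concentrations
  a_uM <- 137.3; roundtrip <- from_mM(as_mM(from_mM(as_mM(a_uM, "uM"),
                                                    "M"), "M"), "uM")
  expect_equal(rate_ping_pong(p, roundtrip, 60),
               rate_ping_pong(p, a_uM, 60), tolerance = 1e-12)
})

test_that("macroscopic parameters follow from elementary constants by the
          defining relations", {
  m <- micro_rates(k1 = 2350, k_m1 = 20, k_nadph = 27, k2 = 1000,
                   k_m2 = 10, k_7hk = 2700, ka = 1, kd = 22)
  p <- macro_from_micro(m, 99)
  expect_equal(from_mM(p$km_nadph, "uM"), 20)    # (20 + 27) / 2350 mM
  expect_equal(p$k_i, 22)                        # kd / ka
  expect_equal(p$k_bim, 1000 * 2700 / (10 + 2700))
  # binding-limited limit: k_m2 = 0 gives k_bim = k2
  m0 <- micro_rates(2350, 20, 27, k2 = 555, k_m2 = 0, k_7hk = 100,
                    ka = 1, kd = 22)
  expect_equal(macro_from_micro(m0, 99)$k_bim, 555)
  expect_error(micro_rates(-1, 1, 1, 1, 1, 1, 1, 1), "non-negative")
})

test_that("micro_from_macro resolves the degeneracy and round-trips
          exactly", {
  p <- ref_params()
  m <- micro_from_macro(p, commitment = 4, excess = 100, ka = 1)
  expect_equal(m$k_nadph, 27)
  expect_equal(m$k_m1, 108)
  expect_equal(m$k1, (108 + 27) / 0.020)
  expect_equal(m$k_7hk, 2700)
  back <- macro_from_micro(m, 99)
  expect_equal(unlist(unclass(back)), unlist(unclass(p)), tolerance = 1e-12)
  # no-inhibition sentinel survives the round trip
  p_inf <- kinetic_params(99, 1490, 27, 20, Inf)
  back_inf <- macro_from_micro(micro_from_macro(p_inf), 99)
  expect_identical(back_inf$k_i, Inf)
  expect_warning(micro_from_macro(p, excess = 1), "degrades")
  expect_error(micro_from_macro(p, commitment = -2), "positive")
})

test_that("parameter YAML serialization round-trips, including the
          no-inhibition sentinel", {
  f <- tempfile(fileext = ".yaml")
  on.exit(unlink(f))
  p <- ref_params()
  params_to_yaml(p, f)
  expect_equal(unlist(unclass(params_from_yaml(f))),
               unlist(unclass(p)))
  params_to_yaml(kinetic_params(99, 1490, 27, 20, Inf), f)
  expect_identical(params_from_yaml(f)$k_i, Inf)
})
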