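test_that("trajectories conserve enzyme, nicotinamide and coumarin totals", {
  p <- ref_params()
  micro <- micro_from_macro(p)
  init <- mechanism_state(0.16, 0.06, p$e_total)
  traj <- simulate_mechanism(micro, init, seq(0, 5, by = 0.02))
  tot <- conserved_totals(traj)
  for (col in names(tot))
    expect_lt(max(abs(tot[[col]] / tot[[col]][1] - 1)), 1e-9)
  expect_true(all(as.matrix(traj[, -1]) > -1e-12))
})

test_that("degenerate mechanisms behave as expected: no enzyme, no
          dead-end channel, no 7HK", {
  p <- ref_params()
  micro <- micro_from_macro(p)
  # no catalyst: metabolites constant
  traj0 <- simulate_mechanism(micro, mechanism_state(0.16, 0.06, 0),
                              seq(0, 2, by = 0.1))
  expect_equal(traj0$nadph, rep(0.16, nrow(traj0)))
  expect_equal(traj0$s7hk, rep(0.06, nrow(traj0)))
  # ka = 0: dead-end complex never populated
  m_free <- micro_from_macro(kinetic_params(99, 1490, 27, 20, Inf))
  expect_identical(m_free$ka, 0)
  traj1 <- simulate_mechanism(m_free, mechanism_state(0.16, 0.06, p$e_total),
                              seq(0, 2, by = 0.1))
  expect_equal(max(abs(traj1$ei)), 0)
  # no 7HK: NADPH consumed only to single-turnover enzyme loading
  traj2 <- simulate_mechanism(micro, mechanism_state(0.16, 0, p$e_total),
                              seq(0, 50, by = 0.5))
  consumed <- traj2$nadph[1] - min(traj2$nadph)
  expect_lte(consumed, p$e_total * (1 + 1e-6))
})

test_that("clamped-substrate steady state matches the closed-form balance
          solution and the rate law within 1% at high excess", {
  p <- ref_params()
  micro <- micro_from_macro(p, excess = 100)
  grid <- expand.grid(a = 10^seq(log10(5e-3), log10(0.2), length.out = 6),
                      b = 10^seq(log10(5e-3), log10(0.15), length.out = 6))
  for (i in seq_len(nrow(grid))) {
    a <- grid$a[i]; b <- grid$b[i]
    v_lin <- steady_state_velocity(micro, a, b, p$e_total)
    expect_equal(v_lin, oracle_full_ss_mM_s(micro, a, b, p$e_total),
                 tolerance = 1e-10)
    v_closed <- as_mM(rate_ping_pong(p, from_mM(a, "uM"), from_mM(b, "uM")),
                      "uM")
    expect_lt(abs(v_lin - v_closed) / v_closed, 0.01)
  }
  expect_identical(steady_state_velocity(micro, 0.16, 0.06, 0), 0)
})

test_that("the discrepancy at low excess equals the neglected denominator
          term exactly", {
  p <- ref_params()
  micro <- suppressWarnings(micro_from_macro(p, excess = 1))
  a <- 0.16; b <- 0.06
  v_full <- steady_state_velocity(micro, a, b, p$e_total)
  v_closed <- as_mM(rate_ping_pong(p, 160, 60), "uM")
  # 1/v_full - 1/v_closed = 1/(k_7hk * E_tot): the single term the closed
  # form drops from the balance denominator
  expect_equal(1 / v_full - 1 / v_closed, 1 / (micro$k_7hk * p$e_total),
               tolerance = 1e-9)
  # and the mismatch grows monotonically as excess -> 1
  mis <- vapply(c(100, 10, 2, 1), function(ex) {
    m <- suppressWarnings(micro_from_macro(p, excess = ex))
    abs(steady_state_velocity(m, a, b, p$e_total) - v_closed) / v_closed
  }, numeric(1))
  expect_true(all(diff(mis) > 0))
})

test_that("early-time mechanism flux agrees with the rate law
          (quasi-steady-state regime)", {
  p <- ref_params()
  micro <- micro_from_macro(p)
  init <- mechanism_state(0.16, 0.06, p$e_total)
  traj <- simulate_mechanism(micro, init, seq(0, 0.5, by = 0.005))
  # instantaneous turnover flux after the enzyme transient (~1/k_nadph)
  i <- which.min(abs(traj$time - 0.3))
  flux <- micro$k_7hk * traj$e3[i]
  v_closed <- as_mM(rate_ping_pong(p, 160, 60), "uM")
  expect_lt(abs(flux - v_closed) / v_closed, 0.01)
  # window-averaged initial velocity matches the clamped steady state
  v_iv <- initial_velocity(traj, "nadp", max_conversion = 0.02)
  v_ss <- steady_state_velocity(micro, 0.16, 0.06, p$e_total)
  expect_lt(abs(v_iv - v_ss) / v_ss, 0.01)
})

test_that("initial_velocity extracts slopes and enforces its window
          contract", {
  lin <- data.frame(time = seq(0, 1, by = 0.1))
  lin$conc <- 3 + 0.5 * lin$time
  expect_equal(initial_velocity(lin, "conc", max_conversion = 1), 0.5)
  expect_error(initial_velocity(lin, "conc", max_conversion = 0), "empty")
  expect_error(initial_velocity(lin, "missing"), "not in trajectory")
  p <- ref_params()
  traj <- simulate_mechanism(micro_from_macro(p),
                             mechanism_state(0.16, 0.06, p$e_total),
                             c(0, 1, 2, 3))
  expect_error(initial_velocity(traj, "nadp", max_conversion = 1e-5),
               "finer")
})
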