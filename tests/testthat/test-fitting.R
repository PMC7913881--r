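test_that("noiseless data are recovered essentially exactly for several
          generating points", {
  cases <- list(c(1490, 27, 20, 22), c(300, 5, 50, 5), c(5000, 100, 8, 200))
  for (th in cases) {
    gen <- kinetic_params(99, th[1], th[2], th[3], th[4])
    d <- generate_velocity_dataset(
      velocity_design(cv = 0, floor_uM_s = 0, extended = TRUE), gen,
      seed = 1)
    fit <- fit_rate_law(d, 99)
    expect_equal(unname(fit$estimates), th, tolerance = 1e-3)
  }
})

test_that("rank-deficient designs are rejected", {
  p <- ref_params()
  d <- generate_velocity_dataset(
    velocity_design(s7hk_uM = c(60, 60), cv = 0), p, seed = 1)
  d$s7hk_uM <- 60
  expect_error(fit_rate_law(d, 99), "rank-deficient")
  expect_error(validate_velocity_dataset(data.frame(nadph_uM = 1)),
               "columns")
})

test_that("the objective is invariant to row order and the fit is
          self-consistent", {
  p <- ref_params()
  d <- generate_velocity_dataset(velocity_design(extended = TRUE), p,
                                 seed = 3)
  fit <- fit_rate_law(d, 99)
  perm <- d[sample.int(nrow(d)), ]
  fit_perm <- fit_rate_law(perm, 99)
  expect_equal(fit_perm$objective, fit$objective, tolerance = 1e-8)
  expect_equal(fit_perm$estimates, fit$estimates, tolerance = 1e-6)
  # refitting noiseless data generated from the fitted point reproduces it
  gen <- fit$params
  d2 <- generate_velocity_dataset(
    velocity_design(cv = 0, floor_uM_s = 0, extended = TRUE),
    gen, seed = 1)
  fit2 <- fit_rate_law(d2, 99)
  expect_equal(fit2$estimates, fit$estimates, tolerance = 1e-3)
})

test_that("estimator bias and RMSE across seeds stay small for the
          well-identified parameters", {
  p <- ref_params()
  truth <- c(1490, 27, 20)
  ests <- t(vapply(1:50, function(s) {
    d <- generate_velocity_dataset(velocity_design(), p, seed = s)
    fit_rate_law(d, 99, starts = 1)$estimates[1:3]
  }, numeric(3)))
  rel <- sweep(ests, 2, truth, "/") - 1
  expect_true(all(abs(colMeans(rel)) < 0.05))          # bias
  expect_true(all(sqrt(colMeans(rel^2)) < 0.15))       # RMSE
})

test_that("K_i is flagged non-identifiable on the routine design and
          profiles flat there, but is pinned by the extended series", {
  p <- ref_params()
  d_std <- generate_velocity_dataset(velocity_design(), p, seed = 7)
  fit_std <- fit_rate_law(d_std, 99)
  expect_false(fit_std$k_i_identifiable)
  prof_std <- profile_likelihood(d_std, fit_std, "k_i_mM",
                                 c(1, 10, 22, 100, 1000))
  # monotone-flat: the objective only falls toward large K_i (no interior
  # minimum), and from the generating 22 mM upward it stays inside the
  # chi-square(1) 95% likelihood increment — the data cannot tell 22 mM
  # from no inhibition at all
  expect_true(all(diff(prof_std$objective) < 0))
  sigma2 <- attr(prof_std, "mle_objective") / (nrow(d_std) - 4)
  excess <- prof_std$objective[prof_std$value >= 22] -
    attr(prof_std, "mle_objective")
  expect_true(all(excess < stats::qchisq(0.95, 1) * sigma2))
  d_ext <- generate_velocity_dataset(velocity_design(extended = TRUE), p,
                                     seed = 7)
  fit_ext <- fit_rate_law(d_ext, 99)
  expect_true(fit_ext$k_i_identifiable)
  grid <- c(5, 11, 22, 44, 100)
  prof_ext <- profile_likelihood(d_ext, fit_ext, "k_i_mM", grid)
  expect_equal(grid[which.min(prof_ext$objective)], 22)
  # profiling at the fitted value reproduces the fit objective
  at_mle <- profile_likelihood(d_ext, fit_ext, "k_i_mM",
                               fit_ext$estimates[["k_i_mM"]])
  expect_equal(at_mle$objective, fit_ext$objective, tolerance = 1e-6)
  expect_error(profile_likelihood(d_ext, fit_ext, "k_i_mM", c(-1, 22)),
               "positive")
  expect_error(profile_likelihood(d_ext, fit_ext, "vmax", 1), "unknown")
})

test_that("bootstrap intervals are deterministic, cover the generating
          parameters, and collapse without noise", {
  p <- ref_params()
  d <- generate_velocity_dataset(velocity_design(extended = TRUE), p,
                                 seed = 42)
  fit <- fit_rate_law(d, 99)
  ci1 <- bootstrap_ci(d, fit, n_boot = 100, seed = 5)
  ci2 <- bootstrap_ci(d, fit, n_boot = 100, seed = 5)
  expect_identical(ci1$lower, ci2$lower)
  expect_identical(ci1$upper, ci2$upper)
  truth <- c(1490, 27, 20, 22)
  expect_true(all(ci1$lower <= truth & truth <= ci1$upper))
  # zero-noise data: every resample is the same dataset, zero-width interval
  d0 <- generate_velocity_dataset(
    velocity_design(cv = 0, floor_uM_s = 0, extended = TRUE), p, seed = 1)
  fit0 <- fit_rate_law(d0, 99)
  ci0 <- bootstrap_ci(d0, fit0, n_boot = 100, seed = 5)
  expect_lt(max((ci0$upper - ci0$lower) / ci0$estimate), 1e-6)
})
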