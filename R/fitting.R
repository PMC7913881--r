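#' Validate a velocity dataset
#'
#' A velocity dataset is a data.frame with columns `nadph_uM`, `s7hk_uM`,
#' `v_uM_per_s` and `replicate`. Fitting requires at least two distinct
#' levels of each substrate (a full-rank design).
#'
#' @param data data.frame to validate.
#' @return the data, invisibly, or an error.
#' @export
validate_velocity_dataset <- function(data) {
  need <- c("nadph_uM", "s7hk_uM", "v_uM_per_s")
  if (!all(need %in% names(data)))
    stop("dataset must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  if (any(data$nadph_uM < 0) || any(data$s7hk_uM < 0))
    stop("negative concentrations in dataset", call. = FALSE)
  if (length(unique(data$nadph_uM)) < 2 || length(unique(data$s7hk_uM)) < 2)
    stop("rank-deficient design: need >= 2 distinct levels per substrate",
         call. = FALSE)
  invisible(data)
}

# run expr with a local RNG stream, restoring the caller's state
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

fit_residuals <- function(log_theta, data, e_total_nM, weighting) {
  # evaluate the rate law directly; clamp so LM line searches that wander
  # to extreme log-parameters see finite residuals instead of errors
  th <- pmin(pmax(exp(log_theta), 1e-12), 1e12)
  e0 <- as_mM(e_total_nM, "nM")
  a <- as_mM(data$nadph_uM, "uM"); b <- as_mM(data$s7hk_uM, "uM")
  num <- e0 * th[1] * th[2] * a * b
  den <- th[2] * a + th[1] * b * (as_mM(th[3], "uM") + a + a * b / th[4])
  pred <- from_mM(ifelse(a == 0 | b == 0, 0, num / den), "uM")
  if (weighting == "relative") {
    eps <- 1e-6 * max(abs(data$v_uM_per_s), 1e-12)
    (data$v_uM_per_s - pred) / (abs(pred) + eps)
  } else {
    data$v_uM_per_s - pred
  }
}

fit_heuristic_start <- function(data, e_total_nM) {
  e_mM <- as_mM(e_total_nM, "nM")
  vmax <- max(data$v_uM_per_s)
  k_nadph0 <- max(as_mM(vmax, "uM") / e_mM, 1e-3) * 1.5     # v <= kcat*E0
  km0 <- exp(mean(log(unique(data$nadph_uM))))               # uM, geometric
  b_lo <- min(data$s7hk_uM[data$s7hk_uM > 0])
  lo <- data[data$s7hk_uM == b_lo & data$v_uM_per_s > 0, , drop = FALSE]
  k_bim0 <- if (nrow(lo) > 0) {
    stats::median(as_mM(lo$v_uM_per_s, "uM") /
                    (e_mM * as_mM(lo$s7hk_uM, "uM")))
  } else 1
  k_i0 <- as_mM(max(data$s7hk_uM), "uM")                     # mM
  pmax(c(k_bim0, k_nadph0, km0, k_i0), 1e-8)
}

#' Fit the ping-pong substrate-inhibition rate law
#'
#' Estimates (k_bim, k_nadph, km_nadph, k_i) from replicated initial
#' velocities by Levenberg-Marquardt least squares on log-parameters
#' (positivity enforced by the parameterization). Total enzyme is fixed at
#' its known value, not estimated. Relative (proportional-error) weighting
#' is the default since velocities span more than an order of magnitude
#' across the design; `"absolute"` gives unweighted residuals. Multiple
#' starts are log-spaced around a marginal-slope heuristic; the best
#' converged solution is returned.
#'
#' @param data velocity dataset (see [validate_velocity_dataset()]).
#' @param e_total_nM total enzyme concentration, nM (fixed).
#' @param weighting `"relative"` or `"absolute"`.
#' @param starts number of starts (>= 1; 8 by default, spanning about
#'   +/- 2 decades around the heuristic).
#' @return object of class `hcde_fit`: `params` ([kinetic_params()] at the
#'   optimum), `estimates` (named vector: k_bim mM^-1 s^-1, k_nadph s^-1,
#'   km_nadph_uM, k_i_mM), `se` (delta-method standard errors), `cov_log`
#'   (covariance of log-estimates), `residuals`, `objective` (weighted SSR),
#'   `converged`, `start_log` (per-start objectives), `k_i_identifiable`
#'   (FALSE when the fitted K_i sits far above the sampled 7HK range, where
#'   the data carry no information about it), plus the inputs.
#' @export
fit_rate_law <- function(data, e_total_nM,
                         weighting = c("relative", "absolute"),
                         starts = 8) {
  validate_velocity_dataset(data)
  weighting <- match.arg(weighting)
  stopifnot(starts >= 1)
  theta0 <- fit_heuristic_start(data, e_total_nM)

  # deterministic log-spaced start perturbations, first start = heuristic
  offsets <- matrix(0, nrow = starts, ncol = 4)
  if (starts > 1) {
    span <- seq(-2, 2, length.out = starts - 1)
    for (j in 1:4)
      offsets[-1, j] <- span[((seq_len(starts - 1) + j) %% (starts - 1)) + 1]
  }

  runs <- vector("list", starts)
  for (i in seq_len(starts)) {
    lt0 <- log(theta0) + log(10) * offsets[i, ]
    runs[[i]] <- tryCatch({
      fit <- minpack.lm::nls.lm(
        par = lt0, fn = fit_residuals, data = data,
        e_total_nM = e_total_nM, weighting = weighting,
        control = minpack.lm::nls.lm.control(maxiter = 500,
                                             ftol = 1e-12, ptol = 1e-12))
      list(par = fit$par, objective = sum(fit$fvec^2),
           converged = fit$info %in% 1:4, info = fit$info)
    }, error = function(e) list(par = lt0, objective = Inf,
                                converged = FALSE, info = conditionMessage(e)))
  }
  objs <- vapply(runs, function(r)
    if (r$converged) r$objective else Inf, numeric(1))
  if (all(!is.finite(objs)))
    stop("no start converged; per-start info: ",
         paste(vapply(runs, function(r) format(r$info)[1], character(1)),
               collapse = "; "), call. = FALSE)
  best <- runs[[which.min(objs)]]
  th <- exp(best$par)
  names(th) <- c("k_bim", "k_nadph", "km_nadph_uM", "k_i_mM")

  # curvature at the optimum (finite-difference Jacobian of residuals)
  r0 <- fit_residuals(best$par, data, e_total_nM, weighting)
  n <- length(r0)
  jac <- matrix(0, n, 4)
  h <- 1e-6
  for (j in 1:4) {
    pp <- best$par; pp[j] <- pp[j] + h
    pm <- best$par; pm[j] <- pm[j] - h
    jac[, j] <- (fit_residuals(pp, data, e_total_nM, weighting) -
                   fit_residuals(pm, data, e_total_nM, weighting)) / (2 * h)
  }
  jtj <- crossprod(jac)
  dof <- max(n - 4, 1)
  sigma2 <- best$objective / dof
  cov_log <- tryCatch(sigma2 * solve(jtj),
                      error = function(e) matrix(NA_real_, 4, 4))
  se <- th * sqrt(pmax(diag(cov_log), 0))  # delta method to natural scale

  structure(list(
    params = kinetic_params(e_total_nM, th[1], th[2], th[3], th[4]),
    estimates = th,
    se = se,
    cov_log = cov_log,
    residuals = r0,
    objective = best$objective,
    converged = TRUE,
    start_log = data.frame(start = seq_len(starts), objective = objs,
                           converged = vapply(runs, `[[`, logical(1),
                                              "converged")),
    k_i_identifiable = th[["k_i_mM"]] < 20 * as_mM(max(data$s7hk_uM), "uM"),
    weighting = weighting,
    e_total_nM = e_total_nM,
    data = data
  ), class = "hcde_fit")
}

#' @export
print.hcde_fit <- function(x, ...) {
  cat("Rate-law fit (", x$weighting, " weighting, objective ",
      format(x$objective, digits = 6), ")\n", sep = "")
  est <- data.frame(estimate = x$estimates, se = x$se)
  rownames(est) <- c("k_bim [mM^-1 s^-1]", "k_NADPH [s^-1]",
                     "Km_NADPH [uM]", "K_i [mM]")
  print(est)
  if (!x$k_i_identifiable)
    cat("note: K_i is unidentifiable (>= design bound); the sampled 7HK",
        "range carries no information about it\n")
  invisible(x)
}

#' Profile likelihood of one parameter
#'
#' Re-optimizes the remaining three parameters at each fixed value of
#' `param` and returns the objective along the grid. A profile that stays
#' flat far above the design range flags practical non-identifiability
#' (K_i on a low-concentration design being the canonical case).
#'
#' @param data velocity dataset used for `fit`.
#' @param fit an [fit_rate_law()] result.
#' @param param one of `"k_bim"`, `"k_nadph"`, `"km_nadph_uM"`, `"k_i_mM"`.
#' @param grid positive values of `param` to profile over.
#' @return data.frame `value`, `objective`, with attribute `mle_objective`.
#' @export
profile_likelihood <- function(data, fit, param, grid) {
  stopifnot(inherits(fit, "hcde_fit"))
  pnames <- c("k_bim", "k_nadph", "km_nadph_uM", "k_i_mM")
  j <- match(param, pnames)
  if (is.na(j)) stop("unknown parameter '", param, "'", call. = FALSE)
  if (any(grid <= 0)) stop("profile grid must be positive", call. = FALSE)
  free <- setdiff(1:4, j)
  obj <- vapply(grid, function(val) {
    resfun <- function(lt_free) {
      lt <- numeric(4)
      lt[free] <- lt_free
      lt[j] <- log(val)
      fit_residuals(lt, data, fit$e_total_nM, fit$weighting)
    }
    start <- log(fit$estimates)[free]
    f <- tryCatch(minpack.lm::nls.lm(
      par = start, fn = resfun,
      control = minpack.lm::nls.lm.control(maxiter = 300)),
      error = function(e) NULL)
    if (is.null(f)) NA_real_ else sum(f$fvec^2)
  }, numeric(1))
  out <- data.frame(value = grid, objective = obj)
  attr(out, "mle_objective") <- fit$objective
  out
}

#' Case-resampling bootstrap confidence intervals
#'
#' Resamples replicate rows with replacement within each concentration cell
#' of the design (the design itself is kept fixed), refits each resample
#' starting from the original estimates, and returns percentile intervals.
#' Deterministic given `seed`; the caller's RNG state is untouched.
#'
#' @param data velocity dataset used for `fit`.
#' @param fit an [fit_rate_law()] result.
#' @param n_boot number of bootstrap resamples (>= 100).
#' @param seed integer seed.
#' @param level confidence level (default 0.95).
#' @return data.frame with one row per parameter: `lower`, `upper`,
#'   `estimate`; attributes `n_fail` (refit failures) and `draws` (matrix of
#'   bootstrap estimates). A warning is attached when >20% of refits fail.
#' @export
bootstrap_ci <- function(data, fit, n_boot = 200, seed = 1, level = 0.95) {
  stopifnot(inherits(fit, "hcde_fit"), n_boot >= 100)
  cells <- split(seq_len(nrow(data)),
                 interaction(data$nadph_uM, data$s7hk_uM, drop = TRUE))
  draws <- with_seed(seed, {
    out <- matrix(NA_real_, n_boot, 4,
                  dimnames = list(NULL, names(fit$estimates)))
    for (b in seq_len(n_boot)) {
      idx <- unlist(lapply(cells, function(ix)
        ix[sample.int(length(ix), length(ix), replace = TRUE)]),
        use.names = FALSE)
      boot_data <- data[idx, , drop = FALSE]
      f <- tryCatch(minpack.lm::nls.lm(
        par = log(fit$estimates), fn = fit_residuals, data = boot_data,
        e_total_nM = fit$e_total_nM, weighting = fit$weighting,
        control = minpack.lm::nls.lm.control(maxiter = 300)),
        error = function(e) NULL)
      if (!is.null(f) && f$info %in% 1:4) out[b, ] <- exp(f$par)
    }
    out
  })
  ok <- stats::complete.cases(draws)
  if (mean(!ok) > 0.2)
    warning(sprintf("bootstrap refit failure rate %.0f%% exceeds 20%%",
                    100 * mean(!ok)))
  alpha <- (1 - level) / 2
  qs <- apply(draws[ok, , drop = FALSE], 2, stats::quantile,
              probs = c(alpha, 1 - alpha))
  res <- data.frame(parameter = names(fit$estimates),
                    estimate = unname(fit$estimates),
                    lower = qs[1, ], upper = qs[2, ], row.names = NULL)
  attr(res, "n_fail") <- sum(!ok)
  attr(res, "draws") <- draws
  res
}
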