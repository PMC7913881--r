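#' Initial state for the mass-action mechanism
#'
#' Concentrations (mM) of the five enzyme species and four metabolites of the
#' HcdE catalytic cycle: E0 (oxidized enzyme), E1 (E-NADPH charge-transfer
#' complex), E2 (reduced enzyme with bound NADP+), E3 (reduced enzyme-7HK
#' complex), Ei (dead-end E1-7HK complex), free NADPH, 7-hydroxycoumarin,
#' NADP+ and the product 7-hydroxy-3,4-dihydrocoumarin.
#'
#' @param nadph_mM,s7hk_mM initial substrate concentrations, mM.
#' @param e_total_mM total enzyme, mM; all enzyme starts as E0.
#' @param nadp_mM,product_mM initial product concentrations, mM (default 0).
#' @return named numeric vector of class `mechanism_state`.
#' @export
mechanism_state <- function(nadph_mM, s7hk_mM, e_total_mM,
                            nadp_mM = 0, product_mM = 0) {
  st <- c(e0 = e_total_mM, e1 = 0, e2 = 0, e3 = 0, ei = 0,
          nadph = nadph_mM, s7hk = s7hk_mM,
          nadp = nadp_mM, s7hkh2 = product_mM)
  stop_if_negative(st, "mechanism state concentrations")
  structure(st, class = c("mechanism_state", "numeric"))
}

mechanism_deriv <- function(t, y, p) {
  with(as.list(c(y, p)), {
    bind_a <- k1 * nadph * e0 - k_m1 * e1       # E0 + NADPH <-> E1
    hydride <- k_nadph * e1                     # E1 -> E2
    bind_b <- k2 * s7hk * e2 - k_m2 * e3        # E2 + 7HK <-> E3
    turn <- k_7hk * e3                          # E3 -> E0 + NADP+ + product
    dead <- ka * s7hk * e1 - kd * ei            # E1 + 7HK <-> Ei
    list(c(
      e0     = -bind_a + turn,
      e1     = bind_a - hydride - dead,
      e2     = hydride - bind_b,
      e3     = bind_b - turn,
      ei     = dead,
      nadph  = -bind_a,
      s7hk   = -bind_b - dead,
      nadp   = turn,
      s7hkh2 = turn
    ))
  })
}

#' Simulate the full mass-action mechanism
#'
#' Integrates the nine-species mass-action ODE system induced by the two
#' half-reactions and the dead-end branch (see [micro_rates()]). NADP+
#' release is lumped into the k_7hk turnover step. The integrator is
#' stiff-capable (`deSolve::lsoda`) with tight tolerances; the returned
#' trajectory conserves total enzyme, total nicotinamide (free NADPH + free
#' NADP+ + cofactor bound in E1, E2, E3, Ei) and total coumarin (free 7HK +
#' product + 7HK bound in E3, Ei) to better than 1e-9 relative.
#'
#' @param micro a [micro_rates()] object.
#' @param init a [mechanism_state()] (mM).
#' @param times strictly increasing time grid, seconds.
#' @param rtol,atol integration tolerances.
#' @return a data.frame of class `mechanism_trajectory`: column `time` plus
#'   one column per species (mM), with the rates and initial state attached
#'   as attributes.
#' @export
simulate_mechanism <- function(micro, init, times, rtol = 1e-10,
                               atol = 1e-14) {
  stopifnot(inherits(micro, "micro_rates"),
            inherits(init, "mechanism_state"))
  if (length(times) < 2 || any(diff(times) <= 0))
    stop("times must be a strictly increasing grid of length >= 2",
         call. = FALSE)
  p <- unlist(unclass(micro))
  out <- deSolve::lsoda(y = unclass(init), times = times,
                        func = mechanism_deriv, parms = p,
                        rtol = rtol, atol = atol)
  if (attr(out, "istate")[1] < 0)
    stop("ODE integration failed; rate magnitudes: ",
         paste(names(p), signif(p, 3), sep = "=", collapse = ", "),
         call. = FALSE)
  traj <- as.data.frame(out)
  attr(traj, "micro") <- micro
  attr(traj, "init") <- init
  class(traj) <- c("mechanism_trajectory", "data.frame")
  traj
}

#' Conserved totals along a trajectory
#'
#' @param traj a trajectory from [simulate_mechanism()].
#' @return data.frame with columns `enzyme`, `nicotinamide`, `coumarin`
#'   (mM), one row per time point.
#' @export
conserved_totals <- function(traj) {
  data.frame(
    enzyme = traj$e0 + traj$e1 + traj$e2 + traj$e3 + traj$ei,
    nicotinamide = traj$nadph + traj$nadp + traj$e1 + traj$e2 +
      traj$e3 + traj$ei,
    coumarin = traj$s7hk + traj$s7hkh2 + traj$e3 + traj$ei
  )
}

#' Steady-state velocity of the clamped-substrate mechanism
#'
#' With both substrates clamped (buffered) the enzyme species settle to a
#' true steady state; the five-species linear balance system is solved
#' exactly and the velocity returned as k_7hk * [E3]. This is the
#' independent oracle for [rate_ping_pong()]: it equals
#' \deqn{v = k_{NADPH} E_{tot} / (K_{m,A}/A + 1 + B/K_i +
#'       k_{NADPH}/(k_{bim} B) + k_{NADPH}/k_{7HK})}
#' i.e. the closed-form rate law plus one extra denominator term
#' k_NADPH/k_7HK that the closed form neglects.
#'
#' @param micro a [micro_rates()] object.
#' @param nadph_mM,s7hk_mM clamped substrate concentrations, mM.
#' @param e_total_mM total enzyme, mM.
#' @return velocity, mM/s.
#' @export
steady_state_velocity <- function(micro, nadph_mM, s7hk_mM, e_total_mM) {
  stopifnot(inherits(micro, "micro_rates"))
  stop_if_negative(c(nadph_mM, s7hk_mM, e_total_mM),
                   "concentrations")
  if (e_total_mM == 0) return(0)
  a <- nadph_mM; b <- s7hk_mM
  with(unclass(micro), {
    # rows: E1, E2, E3, Ei balances; conservation closes the system
    m <- rbind(
      c(k1 * a, -(k_m1 + k_nadph) - ka * b, 0, 0, kd),
      c(0, k_nadph, -k2 * b, k_m2, 0),
      c(0, 0, k2 * b, -(k_m2 + k_7hk), 0),
      c(0, ka * b, 0, 0, -kd),
      c(1, 1, 1, 1, 1)
    )
    rhs <- c(0, 0, 0, 0, e_total_mM)
    if (kd == 0 && ka == 0) { # no dead-end branch: drop Ei
      m <- rbind(m[1:3, 1:4], c(1, 1, 1, 1))
      rhs <- c(0, 0, 0, e_total_mM)
      sol <- tryCatch(solve(m, rhs),
                      error = function(e) stop("singular steady-state system",
                                               call. = FALSE))
      return(k_7hk * sol[4])
    }
    sol <- tryCatch(solve(m, rhs),
                    error = function(e) stop("singular steady-state system",
                                             call. = FALSE))
    k_7hk * sol[4]
  })
}

#' Initial velocity from a trajectory
#'
#' Least-squares slope of one species over the early window in which
#' substrate conversion stays below `max_conversion` (default 5%). The
#' limiting substrate is whichever of NADPH and 7HK has the smaller initial
#' concentration. The returned velocity is positive for product formation
#' and for substrate depletion alike (sign convention: magnitude of the
#' slope).
#'
#' @param traj a trajectory from [simulate_mechanism()], or any data.frame
#'   with a `time` column and the named species column.
#' @param species column to regress (default `"nadp"`).
#' @param max_conversion conversion cap defining the window, in (0, 1].
#' @return velocity in the trajectory's concentration units per second.
#' @export
initial_velocity <- function(traj, species = "nadp", max_conversion = 0.05) {
  if (!species %in% names(traj))
    stop("species '", species, "' not in trajectory", call. = FALSE)
  if (max_conversion <= 0)
    stop("max_conversion must be > 0 (empty window)", call. = FALSE)
  if (all(c("nadph", "s7hk") %in% names(traj))) {
    a0 <- traj$nadph[1]; b0 <- traj$s7hk[1]
    lim <- if (a0 <= b0) "nadph" else "s7hk"
    c0 <- traj[[lim]][1]
    conv <- if (c0 > 0) (c0 - traj[[lim]]) / c0 else rep(0, nrow(traj))
    keep <- conv <= max_conversion
  } else {
    keep <- rep(TRUE, nrow(traj))
  }
  if (sum(keep) < 5)
    stop("fewer than 5 points below the conversion cap; ",
         "use a finer early time grid", call. = FALSE)
  tt <- traj$time[keep]; yy <- traj[[species]][keep]
  abs(stats::cov(tt, yy) / stats::var(tt))
}
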