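#' Propensities of the four elementary element-level processes
#'
#' For a cell holding `mA` autonomous and `mN` nonautonomous elements with
#' replication capacity `li` (the number of replications its balance can
#' still pay for, see [ge_capacity()]):
#' autonomous birth `k1 = rA li mA (mA - 1) / 2` (two A copies interact:
#' replicase plus template), nonautonomous birth `k2 = rN mN mA li`,
#' autonomous death `k3 = dA mA`, nonautonomous death `k4 = dN mN`.
#'
#' @param mA,mN Element counts (non-negative integers).
#' @param li Replication capacity (non-negative integer).
#' @param ge A [ge_params()].
#' @return Named numeric vector `c(k1, k2, k3, k4)`.
#' @examples
#' ge_propensities(3, 2, 10, ge_params(rA = 0.01, rN = 1))
#' @export
ge_propensities <- function(mA, mN, li, ge) {
  stopifnot(inherits(ge, "ge_params"), mA >= 0, mN >= 0, li >= 0)
  k <- cpp_propensities(as.integer(mA), as.integer(mN), as.numeric(li),
                        .ge_clist(ge))
  setNames(k, c("k1", "k2", "k3", "k4"))
}

#' Replication capacity of a cell balance
#'
#' `floor(B / Ec)`: the number of element replications the balance can still
#' fund; 0 when `B < Ec`.
#'
#' @param B Resource balance.
#' @param Ec Cost per replication.
#' @return Non-negative integer-valued numeric.
#' @export
ge_capacity <- function(B, Ec) {
  stopifnot(is.numeric(B), is.numeric(Ec), Ec > 0)
  vapply(B, cpp_capacity, 0, Ec = Ec)
}

#' Sample and apply one elementary element-level event
#'
#' Draws one of the four elementary processes with probability proportional
#' to its propensity and applies it: births increment the element count and
#' charge `Ec` to the balance, deaths decrement the count. When the total
#' propensity is zero the event is a no-op. Waiting times are not tracked:
#' each call is exactly one event.
#'
#' @param cell A list with components `B`, `mA`, `mN`.
#' @param ge A [ge_params()].
#' @return The updated cell list.
#' @export
sample_ge_event <- function(cell, ge) {
  stopifnot(inherits(ge, "ge_params"))
  cpp_ge_event(cell$B, as.integer(cell$mA), as.integer(cell$mN),
               .ge_clist(ge))
}

#' Run the intracellular element phase of one round for one cell
#'
#' Applies exactly `K` elementary events (see [sample_ge_event()]),
#' recomputing the replication capacity `floor(B / Ec)` before each draw, so
#' the elements can draw down at most `K * Ec` resources per round.
#'
#' @param cell A list with components `B`, `mA`, `mN`.
#' @param ge A [ge_params()]; `ge$K` sets the number of events.
#' @return The updated cell list.
#' @export
run_intracellular_round <- function(cell, ge) {
  stopifnot(inherits(ge, "ge_params"))
  cpp_ge_round(cell$B, as.integer(cell$mA), as.integer(cell$mN),
               .ge_clist(ge), ge$K)
}

#' Deterministic consumer-resource limit of the element kinetics
#'
#' Mass-action rate equations for resources `S` and the two element classes
#' in a well-mixed, compartment-free volume with constant resource supply
#' rate `r`:
#' `dS/dt = r - rA S A^2 - rN S A N`,
#' `dA/dt = rA S A^2 - dA A`,
#' `dN/dt = rN S A N - dN N`.
#' The stochastic propensity's combinatorial factor `mA (mA - 1) / 2` is
#' absorbed into `rA` here (the equilibrium classification is invariant to
#' that constant rescaling).
#'
#' In the [deSolve::ode()] signature, `parms` is a list with components
#' `r`, `rA`, `rN`, `dA`, `dN`.
#'
#' @param t Time (unused; autonomous system).
#' @param state Named numeric vector `c(S =, A =, N =)`.
#' @param parms List of rates `r`, `rA`, `rN`, `dA`, `dN`.
#' @return A list holding the derivative vector, as expected by deSolve.
#' @export
ge_ode_rhs <- function(t, state, parms) {
  S <- state[["S"]]; A <- state[["A"]]; N <- state[["N"]]
  birthA <- parms$rA * S * A^2
  birthN <- parms$rN * S * A * N
  list(c(S = parms$r - birthA - birthN,
         A = birthA - parms$dA * A,
         N = birthN - parms$dN * N))
}

#' Integrate the deterministic element kinetics
#'
#' Integrates [ge_ode_rhs()] with a stiff-capable adaptive solver
#' ([deSolve::lsoda]). The horizon is extended (doubled, up to
#' `max_horizon`) until the state changes by less than `steady_tol` over the
#' final 10 percent of the horizon, so the returned end state is close to an
#' attractor.
#'
#' @param init Named numeric vector `c(S =, A =, N =)` of initial values.
#' @param parms List of rates `r`, `rA`, `rN`, `dA`, `dN`.
#' @param horizon Initial integration horizon.
#' @param max_horizon Cap on horizon doubling.
#' @param steady_tol Convergence tolerance on the state change over the
#'   final 10 percent of the horizon.
#' @param atol,rtol Absolute and relative solver tolerances.
#' @param n_out Number of output time points per integration.
#' @return A data.frame with columns `time`, `S`, `A`, `N`; attribute
#'   `"converged"` reports whether the steady-state check passed.
#' @examples
#' traj <- integrate_ge_ode(c(S = 1, A = 5, N = 5),
#'                          list(r = 1, rA = 0.01, rN = 0.005,
#'                               dA = 0.01, dN = 0.01))
#' tail(traj, 1)
#' @export
integrate_ge_ode <- function(init, parms, horizon = 2000,
                             max_horizon = 64000, steady_tol = 1e-6,
                             atol = 1e-10, rtol = 1e-8, n_out = 201) {
  stopifnot(all(c("S", "A", "N") %in% names(init)),
            all(c("r", "rA", "rN", "dA", "dN") %in% names(parms)))
  repeat {
    times <- seq(0, horizon, length.out = n_out)
    sol <- deSolve::ode(y = init[c("S", "A", "N")], times = times,
                        func = ge_ode_rhs, parms = parms,
                        method = "lsoda", atol = atol, rtol = rtol)
    sol <- as.data.frame(sol)
    tail10 <- sol[sol$time >= 0.9 * horizon, c("S", "A", "N")]
    drift <- max(abs(vapply(tail10, function(x) diff(range(x)), 0)))
    if (drift < steady_tol || horizon >= max_horizon) {
      attr(sol, "converged") <- drift < steady_tol
      return(sol)
    }
    horizon <- horizon * 2
  }
}

#' Classify the long-run equilibrium of the compartment-free element model
#'
#' Under the deterministic kinetics of [ge_ode_rhs()], the system has three
#' possible outcomes, decided by the ratio of per-capita birth efficiencies:
#' both classes go extinct when `rN / rA > dN / dA` (the nonautonomous
#' elements overtake, suppress autonomous replication, and then collapse
#' without their replicase), the two classes can coexist only under the
#' fine-tuned equality, and only the autonomous class persists when the
#' inequality is reversed.
#'
#' @param ge A [ge_params()] (only the four rates are used).
#' @param r Resource supply rate (used by the `"ode"` method).
#' @param method `"rule"` applies the analytic condition; `"ode"` integrates
#'   the rate equations from `init` and thresholds the end state.
#' @param init Initial state for the `"ode"` method.
#' @param extinct_tol Abundance below which a class counts as extinct at the
#'   horizon.
#' @param tol Relative tolerance for the equality test of the `"rule"`
#'   method.
#' @param ... Passed to [integrate_ge_ode()].
#' @return One of `"extinction"`, `"autonomous_only"`, `"coexistence"`.
#' @examples
#' classify_equilibrium(ge_params(rA = 0.01, rN = 1), r = 1)   # extinction
#' classify_equilibrium(ge_params(rA = 0.01, rN = 0.005), r = 1)
#' @export
classify_equilibrium <- function(ge, r = 1, method = c("rule", "ode"),
                                 init = c(S = 1, A = 5, N = 5),
                                 extinct_tol = 1e-6, tol = 1e-8, ...) {
  stopifnot(inherits(ge, "ge_params"), ge$rA > 0, ge$dA > 0, ge$dN > 0)
  method <- match.arg(method)
  if (method == "rule") {
    lhs <- ge$rN / ge$rA
    rhs <- ge$dN / ge$dA
    if (abs(lhs - rhs) <= tol * max(lhs, rhs)) return("coexistence")
    return(if (lhs > rhs) "extinction" else "autonomous_only")
  }
  sol <- integrate_ge_ode(init, list(r = r, rA = ge$rA, rN = ge$rN,
                                     dA = ge$dA, dN = ge$dN), ...)
  fin <- sol[nrow(sol), ]
  a_alive <- fin$A > extinct_tol
  n_alive <- fin$N > extinct_tol
  if (a_alive && n_alive) "coexistence"
  else if (a_alive) "autonomous_only"
  else "extinction"
}

#' Stochastic element kinetics in a compartment-free volume
#'
#' Adaptation of the per-round event sampler to a single well-mixed resource
#' pool: each round adds `r` resource units to the pool and then samples
#' `events_per_round` elementary events (propensities as in
#' [ge_propensities()] with capacity `floor(B / Ec)`). Useful to check that
#' the stochastic process reproduces the qualitative regimes of the
#' deterministic limit ([classify_equilibrium()]).
#'
#' @param ge A [ge_params()]; use `Ec = 1` for unit-resource replications.
#' @param r Resource units supplied per round.
#' @param m0A,m0N Initial element counts.
#' @param rounds Number of rounds.
#' @param events_per_round Elementary events sampled per round.
#' @param B0 Initial resource pool.
#' @return A data.frame with columns `round`, `B`, `mA`, `mN`.
#' @export
simulate_ge_stochastic <- function(ge, r, m0A, m0N, rounds,
                                   events_per_round = ge$K, B0 = 0) {
  stopifnot(inherits(ge, "ge_params"), rounds >= 1)
  clist <- .ge_clist(ge)
  B <- B0; mA <- as.integer(m0A); mN <- as.integer(m0N)
  out <- matrix(0, nrow = rounds, ncol = 4,
                dimnames = list(NULL, c("round", "B", "mA", "mN")))
  for (t in seq_len(rounds)) {
    B <- B + r
    res <- cpp_ge_round(B, mA, mN, clist, as.integer(events_per_round))
    B <- res$B; mA <- res$mA; mN <- res$mN
    out[t, ] <- c(t, B, mA, mN)
  }
  as.data.frame(out)
}
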