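#' Create a population state
#'
#' A population state holds parallel vectors describing every protocell
#' (resource balance `B`, element counts `mA`, `mN`, and a type index into
#' `params`), the per-round resource supply `R`, optional genetic-element
#' kinetics, the round counter and a per-round summary history.
#'
#' @param n Number of founding cells per type (recycled to the number of
#'   parameter sets in `params`).
#' @param params A `protocell_params` object or a list of them (one per
#'   competing type, at most two).
#' @param R Resource units supplied per round (positive integer).
#' @param ge Optional [ge_params()] enabling the intracellular element phase.
#' @param init_B Initial balances of founding cells: `"uniform"` draws each
#'   independently from Uniform(0, Etr) (avoids synchronized division
#'   artifacts), `"fixed"` sets them all to `B0`.
#' @param B0 Fixed initial balance when `init_B = "fixed"`.
#'
#' @return An object of class `population_state`.
#' @examples
#' set.seed(1)
#' st <- population_state(30, protocell_params(), R = 30)
#' st
#' @export
population_state <- function(n, params, R = 30, ge = NULL,
                             init_B = c("uniform", "fixed"), B0 = NULL) {
  init_B <- match.arg(init_B)
  if (inherits(params, "protocell_params")) params <- list(params)
  stopifnot(length(params) >= 1, length(params) <= 2,
            all(vapply(params, inherits, TRUE, "protocell_params")),
            is.numeric(R), length(R) == 1, R >= 1, R == as.integer(R))
  if (!is.null(ge)) stopifnot(inherits(ge, "ge_params"))
  n <- rep_len(as.integer(n), length(params))
  type <- rep(seq_along(params), n)
  B <- numeric(length(type))
  for (t in seq_along(params)) {
    idx <- which(type == t)
    B[idx] <- if (init_B == "uniform") {
      runif(length(idx), 0, params[[t]]$Etr)
    } else {
      stopifnot(is.numeric(B0), B0 > 0)
      rep(B0, length(idx))
    }
  }
  structure(list(t = 0L, B = B, mA = integer(length(type)),
                 mN = integer(length(type)), type = type,
                 R = as.integer(R), params = params, ge = ge,
                 history = NULL),
            class = "population_state")
}

#' @export
print.population_state <- function(x, ...) {
  labs <- vapply(x$params, `[[`, "", "type_label")
  counts <- tabulate(x$type, nbins = length(x$params))
  cat(sprintf("<population_state> round %d, %d cells (%s), R=%d%s\n",
              x$t, length(x$B),
              paste(sprintf("%s: %d", labs, counts), collapse = ", "),
              x$R,
              if (is.null(x$ge)) "" else ", with genetic elements"))
  invisible(x)
}

# per-type parameter vectors in engine layout
.tp <- function(params) {
  list(p0 = vapply(params, `[[`, 0, "p0"),
       dE = vapply(params, `[[`, 0, "dE"),
       Etr = vapply(params, `[[`, 0, "Etr"),
       nu = vapply(params, `[[`, 0, "nu"),
       divmode = unname(.divmode_code[
         vapply(params, `[[`, "", "division_mode")]))
}

.update_state <- function(state, res) {
  state$B <- res$B
  state$mA <- res$mA
  state$mN <- res$mN
  state$type <- res$type
  state
}

#' Feeding phase of one round
#'
#' Each cell can acquire at most one resource unit per round. The cell order
#' is randomly permuted and the first `min(R, N)` cells in the permuted order
#' gain one unit; leftover supply is discarded (no carry-over between rounds).
#'
#' @param state A [population_state()].
#' @return The updated state; attribute `"fed"` holds the logical fed
#'   indicator for the round.
#' @export
feed_round <- function(state) {
  stopifnot(inherits(state, "population_state"))
  res <- cpp_feed_round(state$B, state$mA, state$mN, state$type, state$R)
  state <- .update_state(state, res)
  attr(state, "fed") <- res$fed
  state
}

#' Housekeeping phase: pay the per-round cost and cull
#'
#' Every cell's balance is decremented by its type's housekeeping cost `dE`;
#' cells whose resulting balance is not positive are removed.
#'
#' @param state A [population_state()].
#' @return The updated state.
#' @export
pay_housekeeping_and_cull <- function(state) {
  stopifnot(inherits(state, "population_state"))
  tp <- .tp(state$params)
  res <- cpp_housekeep_round(state$B, state$mA, state$mN, state$type,
                             tp$p0, tp$dE, tp$Etr, tp$nu, tp$divmode)
  .update_state(state, res)
}

#' Stochastic death phase
#'
#' Each cell is independently removed with its type's per-round death
#' probability `nu`; with `nu = 0` the operation is the identity.
#'
#' @param state A [population_state()].
#' @return The updated state.
#' @export
apply_stochastic_death <- function(state) {
  stopifnot(inherits(state, "population_state"))
  tp <- .tp(state$params)
  res <- cpp_death_round(state$B, state$mA, state$mN, state$type,
                         tp$p0, tp$dE, tp$Etr, tp$nu, tp$divmode)
  .update_state(state, res)
}

#' Split the resources of a dividing mother cell
#'
#' `"symmetric"` halves the balance; `"random"` draws the first daughter's
#' share uniformly on (0, B). Both modes conserve the balance exactly.
#'
#' @param B Mother balance (positive).
#' @param mode `"symmetric"` or `"random"`.
#' @return Numeric vector `c(B1, B2)` with `B1 + B2 == B`.
#' @examples
#' split_resources(5, "symmetric")
#' @export
split_resources <- function(B, mode = c("random", "symmetric")) {
  mode <- match.arg(mode)
  stopifnot(is.numeric(B), length(B) == 1, B > 0)
  res <- cpp_divide(B, 0L, 0L, .divmode_code[[mode]])
  c(res$B1, res$B2)
}

#' Attempt reproduction of one cell
#'
#' A cell at or above its reproduction threshold divides into two daughters
#' with its successful-reproduction probability (the baseline `p0` for cells
#' without elements, otherwise scaled by the mutualist fraction, see
#' [reproduction_probability()]); otherwise the mother dies and all its
#' resources and elements are lost.
#'
#' @param cell A list with components `B`, `mA`, `mN`.
#' @param params The cell's [protocell_params()].
#' @param ge Optional [ge_params()] (sets the mutualist class).
#' @return A list of two daughter cells on success, or an empty list.
#' @export
attempt_reproduction <- function(cell, params, ge = NULL) {
  stopifnot(inherits(params, "protocell_params"),
            is.numeric(cell$B), cell$mA >= 0, cell$mN >= 0)
  if (cell$B < params$Etr)
    stop("attempt_reproduction() called with B < Etr (B=", cell$B, ")")
  mut_class <- if (is.null(ge) || ge$mutualist_class == "autonomous") 0L
               else 1L
  p <- cpp_repro_prob(as.integer(cell$mA), as.integer(cell$mN),
                      params$p0, mut_class)
  if (runif(1) >= p) return(list())
  d <- cpp_divide(cell$B, as.integer(cell$mA), as.integer(cell$mN),
                  .divmode_code[[params$division_mode]])
  list(list(B = d$B1, mA = d$mA1, mN = d$mN1),
       list(B = d$B2, mA = d$mA2, mN = d$mN2))
}

.summary_row <- function(state) {
  n_types <- length(state$params)
  out <- data.frame(round = state$t)
  for (t in 1:2) {
    idx <- if (t <= n_types) which(state$type == t) else integer()
    out[[paste0("n", t)]] <- if (t <= n_types) length(idx) else NA_real_
    out[[paste0("mean_B", t)]] <-
      if (t <= n_types && length(idx)) mean(state$B[idx]) else NA_real_
  }
  has_ge <- (state$mA + state$mN) > 0
  out$ng <- sum(has_ge)
  out$no <- sum(!has_ge)
  out$sum_mA <- sum(state$mA)
  out$sum_mN <- sum(state$mN)
  out
}

#' Advance the population by one full round
#'
#' Executes, in order: permuted feeding, housekeeping and culling, the
#' intracellular element phase (for element-carrying cells, when `ge` is
#' set), one reproduction attempt for every cell at or above its threshold,
#' and stochastic death (applied to daughters and survivors alike). Newborn
#' daughters first act in the next round. A summary record is appended to
#' `state$history`.
#'
#' @param state A [population_state()].
#' @return The updated state with `t` incremented.
#' @examples
#' set.seed(1)
#' st <- population_state(30, protocell_params(), R = 30)
#' st <- step_round(st)
#' st$history
#' @export
step_round <- function(state) {
  stopifnot(inherits(state, "population_state"))
  tp <- .tp(state$params)
  ge <- if (is.null(state$ge)) NULL else .ge_clist(state$ge)
  res <- cpp_feed_round(state$B, state$mA, state$mN, state$type, state$R)
  res <- cpp_housekeep_round(res$B, res$mA, res$mN, res$type,
                             tp$p0, tp$dE, tp$Etr, tp$nu, tp$divmode)
  if (!is.null(ge))
    res <- cpp_ge_phase_round(res$B, res$mA, res$mN, res$type, ge)
  res <- cpp_reproduction_round(res$B, res$mA, res$mN, res$type,
                                tp$p0, tp$dE, tp$Etr, tp$nu, tp$divmode, ge)
  res <- cpp_death_round(res$B, res$mA, res$mN, res$type,
                         tp$p0, tp$dE, tp$Etr, tp$nu, tp$divmode)
  state <- .update_state(state, res)
  state$t <- state$t + 1L
  state$history <- rbind(state$history, .summary_row(state))
  state
}

#' Run many rounds through the compiled engine
#'
#' Identical round schedule to [step_round()] (the two share the same
#' compiled phase functions and random draws), looped in C++ with a thinned
#' per-round summary.
#'
#' @param state A [population_state()].
#' @param rounds Number of rounds to advance.
#' @param record_every Thinning interval for the summary history; the final
#'   round is always recorded.
#' @return The updated state; `state$history` gains rows with columns
#'   `round`, per-type counts `n1`, `n2` and mean balances, the counts of
#'   element-carrying (`ng`) and element-less (`no`) cells, and the summed
#'   element counts `sum_mA`, `sum_mN`.
#' @export
run_rounds <- function(state, rounds, record_every = 1) {
  stopifnot(inherits(state, "population_state"), rounds >= 1)
  tp <- .tp(state$params)
  ge <- if (is.null(state$ge)) NULL else .ge_clist(state$ge)
  res <- cpp_run(state$B, state$mA, state$mN, state$type,
                 length(state$params), state$R, as.integer(rounds),
                 tp$p0, tp$dE, tp$Etr, tp$nu, tp$divmode, ge,
                 as.integer(record_every))
  hist <- as.data.frame(res$history)
  hist$round <- hist$round + state$t
  state <- .update_state(state, res)
  state$t <- state$t + as.integer(rounds)
  state$history <- rbind(state$history, hist)
  state
}

#' Analytic equilibrium population size of the protocell-only model
#'
#' First-order estimate `R (1 + p) / (2 dE)` of the stationary population
#' size, derived from the round-level resource balance under the
#' approximation that the mean cell balance is half the reproduction
#' threshold. The estimate is documented to fail for `p <= 1/2` (each
#' reproduction then yields less than one expected survivor, so the
#' population declines) and for `dE` approaching 1 (the cost approaches the
#' per-round resource intake); a warning is emitted in those regions.
#'
#' @param R Resource units supplied per round.
#' @param p Successful-reproduction probability.
#' @param dE Housekeeping cost per round.
#' @return The estimated equilibrium population size.
#' @examples
#' equilibrium_estimate(30, 0.6, 0.3) # 80
#' @export
equilibrium_estimate <- function(R, p, dE) {
  stopifnot(is.numeric(R), is.numeric(p), is.numeric(dE), all(dE > 0),
            all(p >= 0), all(p <= 1))
  if (any(p <= 0.5))
    warning("equilibrium estimate is invalid for p <= 1/2 ",
            "(population declines in expectation)")
  if (any(dE >= 1))
    warning("equilibrium estimate is invalid for dE >= 1 ",
            "(housekeeping cost reaches the per-round intake)")
  R * (1 + p) / (2 * dE)
}

#' Evolutionarily neutral reproduction/cost trade-off slope
#'
#' The ratio `dp/dE = (1 + p0) / dE0` along which a joint increase of the
#' reproduction probability and the housekeeping cost leaves the equilibrium
#' population size (see [equilibrium_estimate()]) unchanged to first order.
#'
#' @param p0 Base successful-reproduction probability.
#' @param dE0 Base housekeeping cost (positive).
#' @return The neutral slope.
#' @examples
#' neutral_tradeoff_slope(0.6, 0.2) # 8
#' @export
neutral_tradeoff_slope <- function(p0, dE0) {
  stopifnot(is.numeric(p0), is.numeric(dE0), all(dE0 > 0))
  (1 + p0) / dE0
}
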