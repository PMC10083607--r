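#' Element-dependent successful-reproduction probability
#'
#' A cell carrying elements reproduces successfully with probability
#' `min(p0 (1 + f), 1)` where `f` is the fraction of mutualists among its
#' elements (`mA / (mA + mN)` when the autonomous class is the mutualist,
#' `mN / (mA + mN)` otherwise). Cells without elements, and cells carrying
#' only parasites, reproduce with the baseline `p0`.
#'
#' @param mA,mN Element counts (vectorized).
#' @param p0 Baseline probability in `[0, 1]`.
#' @param mutualist_class `"autonomous"` or `"nonautonomous"`.
#' @return Probabilities in `[p0, 1]`.
#' @examples
#' reproduction_probability(5, 5, 0.6)   # 0.9
#' reproduction_probability(0, 7, 0.6)   # parasite-only: 0.6
#' @export
reproduction_probability <- function(mA, mN, p0,
                                     mutualist_class = c("autonomous",
                                                         "nonautonomous")) {
  mutualist_class <- match.arg(mutualist_class)
  stopifnot(all(mA >= 0), all(mN >= 0), all(p0 >= 0), all(p0 <= 1))
  mc <- if (mutualist_class == "autonomous") 0L else 1L
  mapply(function(a, n, p) cpp_repro_prob(as.integer(a), as.integer(n),
                                          p, mc),
         mA, mN, p0)
}

.divide_pair <- function(cell, code) {
  d <- cpp_divide(cell$B, as.integer(cell$mA), as.integer(cell$mN), code)
  list(list(B = d$B1, mA = d$mA1, mN = d$mN1),
       list(B = d$B2, mA = d$mA2, mN = d$mN2))
}

#' Division with uniform element counts and proportional resources
#'
#' The first daughter's element counts are discrete-uniform draws on
#' `{0, ..., mA}` and `{0, ..., mN}` (independently per class, endpoints
#' included); resources are allocated proportionally to the total element
#' counts, `B1 = B (mA1 + mN1) / (mA + mN)`. A daughter receiving no
#' elements thus starts with zero balance and is culled at its first
#' housekeeping step unless fed.
#'
#' @param cell A list with components `B`, `mA`, `mN`; `mA + mN` must be
#'   positive (element-less cells divide via [split_resources()]).
#' @return A list of two daughter cells; `B`, `mA` and `mN` are conserved
#'   exactly.
#' @export
divide_ge_random <- function(cell) {
  if (cell$mA + cell$mN <= 0)
    stop("divide_ge_random() requires mA + mN > 0; ",
         "element-less cells divide via split_resources()")
  .divide_pair(cell, 3L)
}

#' Division with uniform resources and binomial element counts
#'
#' The first daughter's resource share `B1` is uniform on (0, B); each
#' element is then assigned to it independently with probability `B1 / B`
#' (binomial counts per class). With no elements present this reduces to the
#' plain random resource split.
#'
#' @param cell A list with components `B`, `mA`, `mN` (`B > 0`).
#' @return A list of two daughter cells; `B`, `mA` and `mN` are conserved
#'   exactly.
#' @export
divide_ge_binomial <- function(cell) {
  stopifnot(cell$B > 0)
  .divide_pair(cell, 4L)
}

#' Symmetric division of elements and resources
#'
#' Each element class is halved (integer part to the first daughter) and
#' resources are allocated proportionally to the element counts. With more
#' than one parasite present, no mutualist-only daughter can ever arise from
#' this rule.
#'
#' @param cell A list with components `B`, `mA`, `mN`; `mA + mN` must be
#'   positive.
#' @return A list of two daughter cells; `B`, `mA` and `mN` are conserved
#'   exactly.
#' @export
divide_ge_symmetric <- function(cell) {
  if (cell$mA + cell$mN <= 0)
    stop("divide_ge_symmetric() requires mA + mN > 0")
  .divide_pair(cell, 5L)
}

#' Seed the founding population of a coupled run
#'
#' Creates `Ng0` element-carrying and `No0` element-less protocells. The
#' total element count of the carrying cells is Poisson(`mu`) — one shared
#' draw per simulation by default, or independent per-cell draws (see
#' [seeding_spec()]). Each carrying cell's mutualist count is uniform on
#' `{0, ..., m0}` (endpoints included; expected mutualist fraction 1/2), the
#' remainder are parasites; whether mutualists are the autonomous or the
#' nonautonomous class follows `ge$mutualist_class`. A cell drawing `m0 = 0`
#' is element-less from the start.
#'
#' @param spec A [seeding_spec()].
#' @param params_ge [protocell_params()] of the element-carrying type (use a
#'   `ge_*` division mode).
#' @param params_o [protocell_params()] of the element-less type.
#' @param ge A [ge_params()].
#' @param R Resource units supplied per round.
#' @param init_B,B0 Initial balances of founding cells, as in
#'   [population_state()].
#' @return A [population_state()] with the carrying type first.
#' @export
seed_initial_population <- function(spec, params_ge, params_o, ge, R = 30,
                                    init_B = c("uniform", "fixed"),
                                    B0 = NULL) {
  stopifnot(inherits(spec, "seeding_spec"), inherits(ge, "ge_params"))
  state <- population_state(c(spec$Ng0, spec$No0),
                            list(params_ge, params_o), R = R, ge = ge,
                            init_B = init_B, B0 = B0)
  if (spec$Ng0 > 0) {
    idx <- which(state$type == 1L)
    m0 <- if (spec$per_cell_draw) rpois(length(idx), spec$mu)
          else rep(rpois(1, spec$mu), length(idx))
    # mutualist count uniform on {0, ..., m0}; remainder are parasites
    mut <- vapply(m0, function(m) if (m > 0) sample.int(m + 1, 1) - 1L
                                  else 0L, 0L)
    par <- as.integer(m0) - mut
    if (ge$mutualist_class == "autonomous") {
      state$mA[idx] <- mut
      state$mN[idx] <- par
    } else {
      state$mN[idx] <- mut
      state$mA[idx] <- par
    }
  }
  state
}

#' Probability of a mutualist-only daughter under uniform-count division
#'
#' Closed form for the probability that a fixed daughter produced by
#' [divide_ge_random()] carries at least two mutualists and no parasites
#' (at least two, because an autonomous element needs a second copy to
#' replicate): `1 / (mN + 1) * (1 - 2 / (mA + 1))`, and 0 for `mA <= 1`
#' where the event is impossible.
#'
#' @param mA,mN Mother element counts (vectorized).
#' @return Probabilities in `[0, 1]`.
#' @examples
#' p_mutualist_only_random(3, 2) # 1/6
#' @export
p_mutualist_only_random <- function(mA, mN) {
  stopifnot(all(mA >= 0), all(mN >= 0))
  p <- (1 / (mN + 1)) * (1 - 2 / (mA + 1))
  ifelse(mA <= 1, 0, p)
}

#' Probability of a mutualist-only daughter under binomial division
#'
#' Closed form for the probability that a fixed daughter produced by
#' [divide_ge_binomial()] carries at least two mutualists and no parasites:
#' `1 / (mN + 1) - (1 / (mA + mN + 1)) (1 + mA / (mA + mN))`. This is
#' smaller than [p_mutualist_only_random()] whenever `mA > 1` and
#' `mN >= 1`.
#'
#' @param mA,mN Mother element counts (vectorized); `mA + mN` must be
#'   positive.
#' @return Probabilities in `[0, 1]`.
#' @examples
#' p_mutualist_only_binomial(2, 1) # 1/12
#' @export
p_mutualist_only_binomial <- function(mA, mN) {
  stopifnot(all(mA >= 0), all(mN >= 0), all(mA + mN > 0))
  1 / (mN + 1) - (1 / (mA + mN + 1)) * (1 + mA / (mA + mN))
}
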