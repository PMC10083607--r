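#' Protocell type parameters
#'
#' Bundle of per-type constants governing feeding economics, reproduction and
#' death of one protocell population.
#'
#' @param p0 Probability of successful reproduction for a cell without genetic
#'   elements (or the baseline for element-carrying cells), in `[0, 1]`.
#' @param dE Housekeeping cost per round, in resource units; must be positive.
#'   Every cell pays it each round and dies when its balance is no longer
#'   positive afterwards.
#' @param Etr Reproduction threshold, in resource units; a cell attempts
#'   division once its balance reaches this value.
#' @param nu Per-round stochastic death probability in `[0, 1]` (0 disables
#'   stochastic death).
#' @param division_mode How mother resources (and genetic elements, for the
#'   `ge_*` modes) are allocated to the two daughters: `"symmetric"` (halved
#'   resources), `"random"` (uniform resource split), `"ge_random"` (uniform
#'   element counts, resources proportional to counts), `"ge_binomial"`
#'   (uniform resource split, binomial element counts with the resource share
#'   as parameter) or `"ge_symmetric"` (halved counts, resources proportional
#'   to counts).
#' @param type_label Opaque label used in outputs to distinguish competing
#'   populations.
#'
#' @return An object of class `protocell_params`.
#' @examples
#' protocell_params(p0 = 0.6, dE = 0.3, Etr = 5)
#' @export
protocell_params <- function(p0 = 0.6, dE = 0.3, Etr = 5, nu = 0,
                             division_mode = c("random", "symmetric",
                                               "ge_random", "ge_binomial",
                                               "ge_symmetric"),
                             type_label = "protocell") {
  division_mode <- match.arg(division_mode)
  stopifnot(is.numeric(p0), length(p0) == 1, p0 >= 0, p0 <= 1,
            is.numeric(dE), length(dE) == 1, dE > 0,
            is.numeric(Etr), length(Etr) == 1, Etr > 0,
            is.numeric(nu), length(nu) == 1, nu >= 0, nu <= 1)
  structure(list(p0 = p0, dE = dE, Etr = Etr, nu = nu,
                 division_mode = division_mode,
                 type_label = as.character(type_label)),
            class = "protocell_params")
}

#' @export
print.protocell_params <- function(x, ...) {
  cat(sprintf(
    "<protocell_params '%s'> p0=%g dE=%g Etr=%g nu=%g division=%s\n",
    x$type_label, x$p0, x$dE, x$Etr, x$nu, x$division_mode))
  invisible(x)
}

# integer codes used by the C++ engine
.divmode_code <- c(symmetric = 1L, random = 2L, ge_random = 3L,
                   ge_binomial = 4L, ge_symmetric = 5L)

#' Genetic-element kinetic parameters
#'
#' Rate constants of the intracellular birth-death process of autonomous (A)
#' and nonautonomous (N) genetic elements. Autonomous elements replicate
#' through the interaction of two A copies (replicase plus template);
#' nonautonomous elements replicate only through interaction with an A copy.
#' Each replication costs the host cell `Ec` resource units; `K` elementary
#' events are sampled per round in every element-carrying cell.
#'
#' @param rA,rN Replication rate constants of autonomous and nonautonomous
#'   elements (non-negative).
#' @param dA,dN Death rate constants (non-negative).
#' @param Ec Resource cost per replication event, in resource units; assumed
#'   small compared to the one unit a cell can acquire per round.
#' @param K Number of elementary event draws per round (positive integer).
#' @param mutualist_class Which element class raises the host's reproduction
#'   probability: `"autonomous"` (the default, mutualists replicate
#'   themselves) or `"nonautonomous"` (mutualists depend on autonomous
#'   parasites for replication).
#'
#' @return An object of class `ge_params`.
#' @examples
#' ge_params() # the default competition parameters
#' @export
ge_params <- function(rA = 0.01, rN = 1, dA = 0.01, dN = 0.01, Ec = 0.01,
                      K = 1, mutualist_class = c("autonomous",
                                                 "nonautonomous")) {
  mutualist_class <- match.arg(mutualist_class)
  stopifnot(is.numeric(rA), rA >= 0, is.numeric(rN), rN >= 0,
            is.numeric(dA), dA >= 0, is.numeric(dN), dN >= 0,
            is.numeric(Ec), length(Ec) == 1, Ec > 0,
            is.numeric(K), length(K) == 1, K >= 1, K == as.integer(K))
  structure(list(rA = rA, rN = rN, dA = dA, dN = dN, Ec = Ec,
                 K = as.integer(K), mutualist_class = mutualist_class),
            class = "ge_params")
}

#' @export
print.ge_params <- function(x, ...) {
  cat(sprintf(
    "<ge_params> rA=%g rN=%g dA=%g dN=%g Ec=%g K=%d mutualists=%s\n",
    x$rA, x$rN, x$dA, x$dN, x$Ec, x$K, x$mutualist_class))
  invisible(x)
}

# C++-facing representation (mut_class: 0 autonomous, 1 nonautonomous)
.ge_clist <- function(ge) {
  list(rA = ge$rA, rN = ge$rN, dA = ge$dA, dN = ge$dN, Ec = ge$Ec,
       K = ge$K,
       mut_class = if (ge$mutualist_class == "autonomous") 0L else 1L)
}

#' Initial seeding specification for element-carrying protocells
#'
#' The founding population has `Ng0` element-carrying and `No0` element-less
#' protocells. The total element count per carrying cell is a Poisson(`mu`)
#' draw; by default one shared draw fixes the count for all carrying cells of
#' a simulation (only the mutualist fraction varies between cells), or an
#' independent draw per cell if `per_cell_draw = TRUE`. Each carrying cell's
#' mutualist count is then uniform on `{0, ..., m0}`; the remainder are
#' parasites.
#'
#' @param mu Poisson mean of the initial element count (positive).
#' @param Ng0 Initial number of element-carrying protocells.
#' @param No0 Initial number of element-less protocells.
#' @param per_cell_draw Draw the Poisson count independently per cell instead
#'   of once per simulation.
#'
#' @return An object of class `seeding_spec`.
#' @export
seeding_spec <- function(mu = 100, Ng0 = 30, No0 = 30,
                         per_cell_draw = FALSE) {
  stopifnot(is.numeric(mu), length(mu) == 1, mu > 0,
            is.numeric(Ng0), Ng0 >= 0, Ng0 == as.integer(Ng0),
            is.numeric(No0), No0 >= 0, No0 == as.integer(No0),
            is.logical(per_cell_draw), length(per_cell_draw) == 1)
  structure(list(mu = mu, Ng0 = as.integer(Ng0), No0 = as.integer(No0),
                 per_cell_draw = per_cell_draw),
            class = "seeding_spec")
}

#' @export
print.seeding_spec <- function(x, ...) {
  cat(sprintf("<seeding_spec> mu=%g Ng0=%d No0=%d per_cell_draw=%s\n",
              x$mu, x$Ng0, x$No0, x$per_cell_draw))
  invisible(x)
}

#' Ensemble specification for experiment runners
#'
#' @param M Number of independent replicate simulations.
#' @param T Rounds per simulation.
#' @param base_seed Root seed; replicate `k` runs under seed
#'   `base_seed + k`, making ensembles reproducible and parallelizable.
#' @param record_every Thinning interval for recorded trajectories (the final
#'   round is always recorded).
#'
#' @return An object of class `ensemble_spec`.
#' @export
ensemble_spec <- function(M = 100, T = 3000, base_seed = 1,
                          record_every = 10) {
  stopifnot(M >= 1, M == as.integer(M), T >= 1, T == as.integer(T),
            is.numeric(base_seed), length(base_seed) == 1,
            record_every >= 1, record_every == as.integer(record_every))
  structure(list(M = as.integer(M), T = as.integer(T),
                 base_seed = as.integer(base_seed),
                 record_every = as.integer(record_every)),
            class = "ensemble_spec")
}

#' @export
print.ensemble_spec <- function(x, ...) {
  cat(sprintf("<ensemble_spec> M=%d T=%d base_seed=%d record_every=%d\n",
              x$M, x$T, x$base_seed, x$record_every))
  invisible(x)
}
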