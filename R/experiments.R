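#' Population-wide fractions of the two element classes
#'
#' The fraction of autonomous and of nonautonomous elements among all
#' elements in the population. Both are undefined (returned as `NA`) when no
#' elements exist.
#'
#' @param state A [population_state()], or any list with numeric `mA`, `mN`
#'   vectors.
#' @return Named numeric `c(omega_A =, omega_N =)`; `NA` when the
#'   population holds no elements.
#' @examples
#' ge_fractions(list(mA = c(2, 0), mN = c(2, 4))) # 0.25, 0.75
#' @export
ge_fractions <- function(state) {
  tot <- sum(state$mA) + sum(state$mN)
  if (tot == 0) return(c(omega_A = NA_real_, omega_N = NA_real_))
  c(omega_A = sum(state$mA) / tot, omega_N = sum(state$mN) / tot)
}

#' Relative abundance of one population among two
#'
#' `Ng / (Ng + No)`, undefined (`NA`) when both are zero. Used for the
#' element-carrying vs element-less competition (and, with type counts, for
#' the two-type protocell competition).
#'
#' @param Ng,No Non-negative counts (vectorized).
#' @return Values in `[0, 1]` or `NA`.
#' @examples
#' relative_abundance(80, 0)  # 1
#' relative_abundance(0, 0)   # NA
#' @export
relative_abundance <- function(Ng, No) {
  stopifnot(all(Ng >= 0, na.rm = TRUE), all(No >= 0, na.rm = TRUE))
  ifelse(Ng + No == 0, NA_real_, Ng / (Ng + No))
}

.new_ensemble_result <- function(kind, trajectories, gamma, extra = list(),
                                 config = list()) {
  structure(c(list(kind = kind, trajectories = trajectories,
                   gamma = gamma,
                   gamma_mean = mean(gamma, na.rm = TRUE),
                   n_double_extinct = sum(is.na(gamma)),
                   config = config),
              extra),
            class = "ensemble_result")
}

#' @export
print.ensemble_result <- function(x, ...) {
  cat(sprintf("<ensemble_result '%s'> %d replicates, mean gamma = %.3f",
              x$kind, length(x$gamma), x$gamma_mean))
  if (x$n_double_extinct > 0)
    cat(sprintf(" (%d double-extinct, excluded)", x$n_double_extinct))
  cat("\n")
  if (!is.null(x$grid)) {
    cat("grid:\n")
    print(utils::head(x$grid, 10))
  }
  invisible(x)
}

#' Competition between two element-less protocell populations
#'
#' Two populations with different growth parameters share one resource pool
#' for `spec$T` rounds; the run is repeated over `spec$M` replicates, each
#' under seed `base_seed + replicate`. The reported relative abundance is
#' that of the second (variant) population at the final round.
#'
#' @param params_base,params_variant [protocell_params()] of the preexisting
#'   and the variant population.
#' @param R Resource units supplied per round.
#' @param spec An [ensemble_spec()].
#' @param n0 Initial sizes, recycled to both populations.
#' @param init_B,B0 Founding balances, as in [population_state()].
#' @param keep_trajectories Record thinned per-round counts (disable for
#'   large parameter sweeps).
#' @return An `ensemble_result` with per-replicate final relative abundance
#'   `gamma` of the variant population, their mean `gamma_mean` (replicates
#'   with both populations extinct are recorded as `NA` and excluded), and
#'   optionally long-format `trajectories`.
#' @export
run_protocell_competition <- function(params_base, params_variant, R = 30,
                                      spec = ensemble_spec(M = 20),
                                      n0 = 30,
                                      init_B = c("uniform", "fixed"),
                                      B0 = NULL, keep_trajectories = TRUE) {
  stopifnot(inherits(params_base, "protocell_params"),
            inherits(params_variant, "protocell_params"),
            inherits(spec, "ensemble_spec"))
  rec <- if (keep_trajectories) spec$record_every else spec$T
  gamma <- rep(NA_real_, spec$M)
  trajs <- vector("list", spec$M)
  for (k in seq_len(spec$M)) {
    set.seed(spec$base_seed + k)
    st <- population_state(n0, list(params_base, params_variant), R = R,
                           init_B = init_B, B0 = B0)
    st <- run_rounds(st, spec$T, record_every = rec)
    fin <- st$history[nrow(st$history), ]
    gamma[k] <- relative_abundance(fin$n2, fin$n1)
    if (keep_trajectories)
      trajs[[k]] <- data.frame(replicate = k,
                               st$history[, c("round", "n1", "n2",
                                              "mean_B1", "mean_B2")])
  }
  .new_ensemble_result(
    "protocell_competition",
    if (keep_trajectories) do.call(rbind, trajs) else NULL,
    gamma,
    config = list(base = unclass(params_base),
                  variant = unclass(params_variant), R = R, n0 = n0,
                  spec = unclass(spec)))
}

#' Competition between element-carrying and element-less protocells
#'
#' The founding population mixes `seeding$Ng0` element-carrying protocells
#' (division scenario `division`) and `seeding$No0` element-less ones
#' (division mode `geless_division`), sharing one resource pool. Both types
#' use the same baseline `p0`, housekeeping cost, threshold and death rate
#' from `params`; carrying cells additionally run `ge$K` element-level
#' events per round and reproduce with the mutualist-fraction-scaled
#' probability. A carrying cell that loses all elements counts as
#' element-less from then on.
#'
#' @param params Baseline [protocell_params()] shared by both types (its
#'   `division_mode` is ignored; see `division` and `geless_division`).
#' @param ge A [ge_params()].
#' @param seeding A [seeding_spec()].
#' @param division Division scenario of the element-carrying type.
#' @param geless_division Division mode of the element-less type.
#' @param R Resource units supplied per round.
#' @param spec An [ensemble_spec()].
#' @param init_B,B0 Founding balances, as in [population_state()].
#' @param keep_trajectories Record thinned per-round counts and element
#'   fractions.
#' @return An `ensemble_result`: per-replicate final relative abundance
#'   `gamma` of element-carrying cells, `gamma_mean`, logical `ge_extinct`
#'   (no elements left at the horizon), and optionally long-format
#'   `trajectories` with columns `replicate`, `round`, `ng`, `no`,
#'   `omega_A`, `omega_N`.
#' @export
run_ge_competition <- function(params, ge, seeding = seeding_spec(),
                               division = c("ge_random", "ge_binomial",
                                            "ge_symmetric"),
                               geless_division = "random", R = 30,
                               spec = ensemble_spec(M = 100),
                               init_B = c("uniform", "fixed"), B0 = NULL,
                               keep_trajectories = TRUE) {
  stopifnot(inherits(params, "protocell_params"),
            inherits(ge, "ge_params"), inherits(seeding, "seeding_spec"),
            inherits(spec, "ensemble_spec"))
  division <- match.arg(division)
  p_ge <- protocell_params(p0 = params$p0, dE = params$dE,
                           Etr = params$Etr, nu = params$nu,
                           division_mode = division,
                           type_label = "ge_containing")
  p_o <- protocell_params(p0 = params$p0, dE = params$dE,
                          Etr = params$Etr, nu = params$nu,
                          division_mode = geless_division,
                          type_label = "ge_less")
  rec <- if (keep_trajectories) spec$record_every else spec$T
  gamma <- rep(NA_real_, spec$M)
  ge_extinct <- logical(spec$M)
  trajs <- vector("list", spec$M)
  for (k in seq_len(spec$M)) {
    set.seed(spec$base_seed + k)
    st <- seed_initial_population(seeding, p_ge, p_o, ge, R = R,
                                  init_B = init_B, B0 = B0)
    st <- run_rounds(st, spec$T, record_every = rec)
    fin <- st$history[nrow(st$history), ]
    gamma[k] <- relative_abundance(fin$ng, fin$no)
    ge_extinct[k] <- (fin$sum_mA + fin$sum_mN) == 0
    if (keep_trajectories) {
      h <- st$history
      tot <- h$sum_mA + h$sum_mN
      trajs[[k]] <- data.frame(
        replicate = k, round = h$round, ng = h$ng, no = h$no,
        omega_A = ifelse(tot == 0, NA_real_, h$sum_mA / tot),
        omega_N = ifelse(tot == 0, NA_real_, h$sum_mN / tot))
    }
  }
  .new_ensemble_result(
    "ge_competition",
    if (keep_trajectories) do.call(rbind, trajs) else NULL,
    gamma,
    extra = list(ge_extinct = ge_extinct),
    config = list(params = unclass(params), ge = unclass(ge),
                  seeding = unclass(seeding), division = division,
                  geless_division = geless_division, R = R,
                  spec = unclass(spec)))
}

#' Phase diagram of the coupled competition over K and Etr
#'
#' Runs [run_ge_competition()] on a lattice of event counts `K` and
#' reproduction thresholds `Etr` and records the ensemble-mean final
#' relative abundance of element-carrying protocells per lattice point.
#'
#' @param params Baseline [protocell_params()] (its `Etr` is overridden by
#'   the lattice).
#' @param ge Baseline [ge_params()] (its `K` is overridden; `rN` is set to
#'   `rA * rn_over_ra`).
#' @param K_values,Etr_values Lattice coordinates.
#' @param division Division scenario of the element-carrying type.
#' @param rn_over_ra Ratio of nonautonomous to autonomous replication rate
#'   constants.
#' @param seeding,R,spec,geless_division As in [run_ge_competition()].
#' @return An `ensemble_result` whose `grid` is a data.frame with columns
#'   `K`, `Etr`, `gamma_mean`, `n_replicates`; `gamma` holds the grid means.
#' @export
run_phase_diagram <- function(params, ge, K_values = 2:10,
                              Etr_values = 2:10,
                              division = c("ge_random", "ge_binomial",
                                           "ge_symmetric"),
                              rn_over_ra = 100,
                              seeding = seeding_spec(), R = 30,
                              spec = ensemble_spec(M = 100),
                              geless_division = "random") {
  division <- match.arg(division)
  grid <- expand.grid(K = as.integer(K_values),
                      Etr = as.numeric(Etr_values))
  grid$gamma_mean <- NA_real_
  grid$n_replicates <- spec$M
  for (i in seq_len(nrow(grid))) {
    p_i <- protocell_params(p0 = params$p0, dE = params$dE,
                            Etr = grid$Etr[i], nu = params$nu,
                            division_mode = params$division_mode,
                            type_label = params$type_label)
    g_i <- ge_params(rA = ge$rA, rN = ge$rA * rn_over_ra, dA = ge$dA,
                     dN = ge$dN, Ec = ge$Ec, K = grid$K[i],
                     mutualist_class = ge$mutualist_class)
    res <- run_ge_competition(p_i, g_i, seeding, division = division,
                              geless_division = geless_division, R = R,
                              spec = spec, keep_trajectories = FALSE)
    grid$gamma_mean[i] <- res$gamma_mean
  }
  .new_ensemble_result(
    "phase_diagram", NULL, grid$gamma_mean,
    extra = list(grid = grid),
    config = list(params = unclass(params), ge = unclass(ge),
                  division = division, rn_over_ra = rn_over_ra,
                  seeding = unclass(seeding), R = R,
                  spec = unclass(spec)))
}

#' Trade-off heatmap between reproduction probability and housekeeping cost
#'
#' Competes variant populations `(p0 + dp, dE0 + de)` against the base
#' population `(p0, dE0)` over a grid of increments and records the
#' ensemble-mean final relative abundance of the variant.
#'
#' @param dp_values,de_values Grids of increments of the reproduction
#'   probability and the housekeeping cost.
#' @param division Division mode used by both populations.
#' @param nu Stochastic death probability shared by both populations.
#' @param p0,dE0 Base parameter values.
#' @param Etr Reproduction threshold shared by both populations.
#' @param R Resource units supplied per round.
#' @param spec An [ensemble_spec()].
#' @param n0 Initial size of each population.
#' @return An `ensemble_result` whose `grid` is a data.frame with columns
#'   `dp`, `de`, `gamma_mean`, `n_replicates`.
#' @export
run_tradeoff_grid <- function(dp_values, de_values,
                              division = c("symmetric", "random"),
                              nu = 0, p0 = 0.6, dE0 = 0.2, Etr = 5,
                              R = 30, spec = ensemble_spec(M = 20),
                              n0 = 30) {
  division <- match.arg(division)
  base <- protocell_params(p0 = p0, dE = dE0, Etr = Etr, nu = nu,
                           division_mode = division, type_label = "base")
  grid <- expand.grid(dp = dp_values, de = de_values)
  grid$gamma_mean <- NA_real_
  grid$n_replicates <- spec$M
  for (i in seq_len(nrow(grid))) {
    variant <- protocell_params(p0 = min(1, p0 + grid$dp[i]),
                                dE = dE0 + grid$de[i], Etr = Etr,
                                nu = nu, division_mode = division,
                                type_label = "variant")
    res <- run_protocell_competition(base, variant, R = R, spec = spec,
                                     n0 = n0, keep_trajectories = FALSE)
    grid$gamma_mean[i] <- res$gamma_mean
  }
  .new_ensemble_result(
    "tradeoff_grid", NULL, grid$gamma_mean,
    extra = list(grid = grid),
    config = list(division = division, nu = nu, p0 = p0, dE0 = dE0,
                  Etr = Etr, R = R, spec = unclass(spec), n0 = n0))
}

#' Smallest winning reproduction-probability increment at a fixed cost
#' increment
#'
#' From a [run_tradeoff_grid()] result, the smallest `dp` whose ensemble
#' mean relative abundance exceeds `threshold` in the grid column with cost
#' increment `de`; `Inf` when no grid point wins.
#'
#' @param result An `ensemble_result` from [run_tradeoff_grid()] (or its
#'   `grid` data.frame).
#' @param de The fixed cost increment (must match a grid value).
#' @param threshold Winning threshold on the mean relative abundance.
#' @return The smallest winning `dp`, or `Inf`.
#' @export
minimal_winning_dp <- function(result, de, threshold = 0.5) {
  grid <- if (inherits(result, "ensemble_result")) result$grid else result
  rows <- grid[abs(grid$de - de) < 1e-12, ]
  if (nrow(rows) == 0) stop("no grid rows with de = ", de)
  win <- rows$dp[rows$gamma_mean > threshold]
  if (length(win) == 0) Inf else min(win)
}
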