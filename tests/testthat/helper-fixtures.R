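# Shared fixture builders. The "standard" parameter set is the coupled
# competition default: R = 30, p0 = 0.6, dE = 0.3, Etr = 5, rA = 0.01,
# rN = 1, dA = dN = 0.01, Ec = 0.01, mu = 100.

std_protocell <- function(...) {
  args <- modifyList(list(p0 = 0.6, dE = 0.3, Etr = 5), list(...))
  do.call(protocell_params, args)
}

std_ge <- function(...) {
  args <- modifyList(list(rA = 0.01, rN = 1, dA = 0.01, dN = 0.01,
                          Ec = 0.01, K = 1), list(...))
  do.call(ge_params, args)
}

# a population state with fully specified balances (bypasses random init)
state_with <- function(B, mA = 0L, mN = 0L, params = std_protocell(),
                       R = 30, ge = NULL) {
  n <- length(B)
  st <- population_state(n, params, R = R, ge = ge, init_B = "fixed",
                         B0 = 1)
  st$B <- as.numeric(B)
  st$mA <- rep_len(as.integer(mA), n)
  st$mN <- rep_len(as.integer(mN), n)
  st
}

# ensemble mean population size over a round window, protocell-only model
mean_population <- function(division, reps, rounds = 3000,
                            window = c(2000, 3000), base_seed = 7000,
                            p0 = 0.6, dE = 0.3, Etr = 5, nu = 0, R = 30) {
  per_rep <- vapply(seq_len(reps), function(k) {
    set.seed(base_seed + k)
    st <- population_state(30, protocell_params(p0 = p0, dE = dE,
                                                Etr = Etr, nu = nu,
                                                division_mode = division),
                           R = R)
    st <- run_rounds(st, rounds, record_every = 1)
    h <- st$history
    mean(h$n1[h$round >= window[1] & h$round <= window[2]])
  }, 0)
  mean(per_rep)
}
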