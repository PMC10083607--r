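test_that("feeding gives one unit to min(R, N) cells and discards the rest", {
  set.seed(1)
  # supply exceeds demand: every cell fed
  st <- state_with(rep(1, 20), R = 30)
  fed <- feed_round(st)
  expect_equal(fed$B, rep(2, 20))
  expect_true(all(attr(fed, "fed")))

  # demand exceeds supply: exactly R cells fed
  st <- state_with(rep(1, 50), R = 30)
  fed <- feed_round(st)
  expect_equal(sum(attr(fed, "fed")), 30)
  expect_equal(sum(fed$B), 50 + 30)
  expect_true(all(fed$B %in% c(1, 2)))

  # different seeds: different fed sets, same fed count
  set.seed(11); f1 <- attr(feed_round(st), "fed")
  set.seed(12); f2 <- attr(feed_round(st), "fed")
  expect_equal(sum(f1), 30)
  expect_equal(sum(f2), 30)
  expect_false(all(f1 == f2))

  # empty population is a no-op
  empty <- state_with(numeric(0))
  expect_equal(length(feed_round(empty)$B), 0)
})

test_that("housekeeping removes cells at or below zero balance, inclusive", {
  st <- state_with(c(0.2, 1.0, 0.3), params = std_protocell(dE = 0.3))
  out <- pay_housekeeping_and_cull(st)
  # B = 0.2 dies (0.2 - 0.3 <= 0), B = 0.3 dies on the boundary (== 0)
  expect_equal(out$B, 0.7)
  # a population with B == dE everywhere empties completely
  st <- state_with(rep(0.3, 10), params = std_protocell(dE = 0.3))
  expect_equal(length(pay_housekeeping_and_cull(st)$B), 0)
})

test_that("resource splitting conserves the balance in both modes", {
  expect_equal(split_resources(5, "symmetric"), c(2.5, 2.5))
  set.seed(2)
  draws <- t(replicate(10000, split_resources(5, "random")))
  expect_true(all(draws > 0 & draws < 5))
  expect_equal(rowSums(draws), rep(5, 10000))
  # first share uniform on (0, 5): mean near 2.5, KS test at alpha = 0.01
  expect_lt(abs(mean(draws[, 1]) - 2.5), 3 * 5 / sqrt(12) / 100)
  ks <- suppressWarnings(stats::ks.test(draws[, 1], "punif", 0, 5))
  expect_gt(ks$p.value, 0.01)
})

test_that("reproduction is all-or-nothing with the configured probability", {
  cell <- list(B = 6, mA = 0L, mN = 0L)
  # p = 1: always two daughters conserving B; p = 0: mother always dies
  set.seed(3)
  d <- attempt_reproduction(cell, std_protocell(p0 = 1,
                                                division_mode = "random"))
  expect_length(d, 2)
  expect_equal(d[[1]]$B + d[[2]]$B, 6)
  expect_length(
    attempt_reproduction(cell, std_protocell(p0 = 0)), 0)
  # below threshold the call is a contract violation
  expect_error(
    attempt_reproduction(list(B = 4.9, mA = 0L, mN = 0L),
                         std_protocell(Etr = 5)),
    "B < Etr")
  # Monte-Carlo success fraction matches p within 3 binomial SEs
  set.seed(4)
  p <- std_protocell(p0 = 0.6)
  succ <- vapply(1:10000, function(i)
    length(attempt_reproduction(cell, p)) == 2, TRUE)
  expect_lt(abs(mean(succ) - 0.6), 3 * sqrt(0.6 * 0.4 / 10000))
})

test_that("stochastic death removes cells independently at rate nu", {
  st <- state_with(rep(1, 100), params = std_protocell(nu = 0))
  expect_equal(length(apply_stochastic_death(st)$B), 100)
  st <- state_with(rep(1, 100), params = std_protocell(nu = 1))
  expect_equal(length(apply_stochastic_death(st)$B), 0)
  set.seed(5)
  st <- state_with(rep(1, 10000), params = std_protocell(nu = 0.01))
  removed <- 10000 - length(apply_stochastic_death(st)$B)
  expect_lt(abs(removed - 100), 30) # 3 binomial SEs
})

test_that("one round follows feed, housekeep, reproduce in order", {
  # hand-trace: B = 4.5, fed to 5.5, pays 0.3 -> 5.2 >= Etr = 5, p0 = 1:
  # the single cell must turn into exactly two daughters with total B 5.2
  set.seed(6)
  st <- state_with(4.5, params = std_protocell(p0 = 1, dE = 0.3, Etr = 5,
                                               division_mode = "random"),
                   R = 30)
  st <- step_round(st)
  expect_equal(length(st$B), 2)
  expect_equal(sum(st$B), 4.5 + 1 - 0.3)
  expect_equal(st$t, 1L)
  expect_equal(nrow(st$history), 1)

  # an empty population stays empty but history still grows
  empty <- state_with(numeric(0))
  empty <- step_round(empty)
  expect_equal(length(empty$B), 0)
  expect_equal(empty$history$n1, 0)
})

test_that("stepwise rounds and the compiled multi-round loop are identical", {
  p1 <- std_protocell(division_mode = "ge_random", type_label = "g")
  p2 <- std_protocell(division_mode = "random", type_label = "o")
  ge <- std_ge(K = 3)
  make <- function() {
    set.seed(77)
    st <- seed_initial_population(seeding_spec(mu = 50, Ng0 = 15,
                                               No0 = 15),
                                  p1, p2, ge, R = 30)
    st
  }
  a <- make()
  for (i in 1:60) a <- step_round(a)
  b <- make()
  b <- run_rounds(b, 60, record_every = 1)
  expect_identical(a$B, b$B)
  expect_identical(a$mA, b$mA)
  expect_identical(a$mN, b$mN)
  expect_identical(a$type, b$type)
  expect_equal(as.data.frame(a$history), as.data.frame(b$history))
})

test_that("equilibrium estimate and its validity warnings", {
  expect_equal(equilibrium_estimate(30, 0.6, 0.3), 80)
  expect_equal(equilibrium_estimate(30, 1, 0.3), 100)
  expect_equal(equilibrium_estimate(60, 0.6, 0.3), 160) # linear in R
  expect_warning(equilibrium_estimate(30, 0.4, 0.3), "p <= 1/2")
  expect_warning(equilibrium_estimate(30, 0.6, 1.2), "dE >= 1")
})

test_that("neutral trade-off slope leaves the equilibrium size invariant", {
  expect_equal(neutral_tradeoff_slope(0.6, 0.2), 8)
  expect_equal(neutral_tradeoff_slope(0, 1), 1)
  # finite-difference check: along the slope the estimate is unchanged to
  # first order
  de <- 1e-6
  dp <- neutral_tradeoff_slope(0.6, 0.2) * de
  n0 <- equilibrium_estimate(30, 0.6, 0.2)
  n1 <- equilibrium_estimate(30, 0.6 + dp, 0.2 + de)
  expect_lt(abs(n1 - n0) / n0, 1e-9)
})

test_that("stochastic death lowers, and p <= 1/2 erodes, the population", {
  # same conditions apart from nu: the nu > 0 equilibrium is smaller
  n_nu0 <- mean_population("random", reps = 3, rounds = 1500,
                           window = c(1000, 1500), base_seed = 8100)
  n_nu <- mean_population("random", reps = 3, rounds = 1500,
                          window = c(1000, 1500), base_seed = 8100,
                          nu = 0.05)
  expect_lt(n_nu, n_nu0)
  # p <= 1/2 with non-binding resources: expected decline
  set.seed(9)
  st <- population_state(200, protocell_params(p0 = 0.4, dE = 0.3,
                                               Etr = 2,
                                               division_mode = "random"),
                         R = 100000)
  st <- run_rounds(st, 200, record_every = 200)
  expect_lt(length(st$B), 200)
})
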