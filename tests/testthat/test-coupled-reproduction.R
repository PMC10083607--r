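test_that("reproduction probability scales with the mutualist fraction", {
  expect_equal(reproduction_probability(0, 7, 0.6), 0.6) # parasite-only
  expect_equal(reproduction_probability(10, 0, 0.6), 1)  # capped at 1
  expect_equal(reproduction_probability(5, 5, 0.6), 0.9)
  expect_equal(reproduction_probability(0, 0, 0.6), 0.6) # element-less
  # swapped mutualist class
  expect_equal(reproduction_probability(7, 0, 0.6, "nonautonomous"), 0.6)
  expect_equal(reproduction_probability(5, 5, 0.6, "nonautonomous"), 0.9)
  # monotone non-decreasing in the mutualist count at fixed total, and
  # always inside [p0, 1]
  for (tot in c(1, 4, 9, 30)) {
    p <- reproduction_probability(0:tot, tot:0, 0.55)
    expect_true(all(diff(p) >= 0))
    expect_true(all(p >= 0.55 & p <= 1))
  }
})

test_that("all division operators conserve resources and element counts", {
  set.seed(41)
  ops <- list(divide_ge_random, divide_ge_binomial, divide_ge_symmetric)
  for (i in 1:200) {
    cell <- list(B = runif(1, 0.1, 20), mA = sample(0:30, 1),
                 mN = sample(0:30, 1))
    if (cell$mA + cell$mN == 0) cell$mA <- 1L
    for (op in ops) {
      d <- op(cell)
      expect_equal(d[[1]]$B + d[[2]]$B, cell$B)
      expect_equal(d[[1]]$mA + d[[2]]$mA, cell$mA)
      expect_equal(d[[1]]$mN + d[[2]]$mN, cell$mN)
      expect_true(all(c(d[[1]]$mA, d[[1]]$mN, d[[2]]$mA, d[[2]]$mN) >= 0))
      expect_gte(d[[1]]$B, 0)
      expect_gte(d[[2]]$B, 0)
    }
  }
})

test_that("uniform-count division: degenerate cases and contracts", {
  set.seed(42)
  # parasite-free mother: daughters never get parasites, resources track
  # the mutualist share
  for (i in 1:50) {
    d <- divide_ge_random(list(B = 8, mA = 4L, mN = 0L))
    expect_equal(d[[1]]$mN, 0)
    expect_equal(d[[1]]$B, 8 * d[[1]]$mA / 4)
  }
  expect_error(divide_ge_random(list(B = 1, mA = 0L, mN = 0L)),
               "mA \\+ mN > 0")
  expect_error(divide_ge_symmetric(list(B = 1, mA = 0L, mN = 0L)),
               "mA \\+ mN > 0")
})

test_that("binomial division with no elements is a plain random split", {
  set.seed(43)
  d <- replicate(2000, divide_ge_binomial(list(B = 5, mA = 0L,
                                               mN = 0L))[[1]]$B)
  expect_true(all(d > 0 & d < 5))
  ks <- suppressWarnings(stats::ks.test(d, "punif", 0, 5))
  expect_gt(ks$p.value, 0.01)
})

test_that("symmetric division halves counts and cannot purge parasites", {
  d <- divide_ge_symmetric(list(B = 10, mA = 4L, mN = 6L))
  expect_equal(c(d[[1]]$mA, d[[1]]$mN), c(2, 3))
  expect_equal(c(d[[2]]$mA, d[[2]]$mN), c(2, 3))
  expect_equal(d[[1]]$B, 5)
  d <- divide_ge_symmetric(list(B = 10, mA = 5L, mN = 0L))
  expect_equal(c(d[[1]]$mA, d[[2]]$mA), c(2, 3))
  expect_equal(d[[1]]$B, 10 * 2 / 5)
  # with more than one parasite, a mutualist-only daughter is impossible
  for (mA in 2:8) for (mN in 2:8) {
    d <- divide_ge_symmetric(list(B = 1, mA = mA, mN = mN))
    expect_gt(d[[1]]$mN, 0)
    expect_gt(d[[2]]$mN, 0)
  }
})

test_that("mutualist-only daughter probability: uniform-count closed form", {
  # exhaustive enumeration over the (mA+1)(mN+1) equiprobable allocations
  oracle <- function(mA, mN) {
    alloc <- expand.grid(a = 0:mA, n = 0:mN)
    mean(alloc$a > 1 & alloc$n == 0)
  }
  for (mA in 0:20) for (mN in 0:20) {
    expect_equal(p_mutualist_only_random(mA, mN), oracle(mA, mN),
                 tolerance = 1e-12)
  }
  expect_equal(p_mutualist_only_random(1, 3), 0)
  expect_equal(p_mutualist_only_random(100, 0), 1 - 2 / 101)
  # Monte-Carlo cross-check through the division operator itself
  set.seed(44)
  hits <- vapply(1:20000, function(i) {
    d <- divide_ge_random(list(B = 1, mA = 3L, mN = 2L))[[1]]
    d$mA > 1 && d$mN == 0
  }, TRUE)
  p <- 1 / 6
  expect_lt(abs(mean(hits) - p), 3 * sqrt(p * (1 - p) / 20000))
})

test_that("mutualist-only daughter probability: binomial closed form", {
  # oracle: integrate P(no parasite) * P(at least two mutualists) over the
  # uniform resource share
  oracle <- function(mA, mN) {
    stats::integrate(function(x) {
      (1 - x)^mN * stats::pbinom(1, mA, x, lower.tail = FALSE)
    }, 0, 1, rel.tol = 1e-12)$value
  }
  for (mA in 0:20) for (mN in 0:20) {
    if (mA + mN == 0) next
    expect_equal(p_mutualist_only_binomial(mA, mN), oracle(mA, mN),
                 tolerance = 1e-9)
  }
  expect_equal(p_mutualist_only_binomial(2, 1), 1 / 12)
  expect_equal(p_mutualist_only_binomial(2, 0), 1 / 3)
  # the binomial rule is strictly worse at producing mutualist-only
  # daughters than the uniform-count rule
  for (mA in 2:20) for (mN in 1:20) {
    expect_lt(p_mutualist_only_binomial(mA, mN),
              p_mutualist_only_random(mA, mN))
  }
  # Monte-Carlo cross-check through the division operator
  set.seed(45)
  hits <- vapply(1:20000, function(i) {
    d <- divide_ge_binomial(list(B = 1, mA = 2L, mN = 1L))[[1]]
    d$mA > 1 && d$mN == 0
  }, TRUE)
  p <- 1 / 12
  expect_lt(abs(mean(hits) - p), 3 * sqrt(p * (1 - p) / 20000))
})

test_that("seeding draws Poisson totals and uniform mutualist fractions", {
  p_ge <- std_protocell(division_mode = "ge_random")
  p_o <- std_protocell(division_mode = "random")
  ge <- std_ge()
  # shared draw: every carrying cell holds the same total
  set.seed(46)
  st <- seed_initial_population(seeding_spec(mu = 100, Ng0 = 30,
                                             No0 = 30), p_ge, p_o, ge)
  tot <- (st$mA + st$mN)[st$type == 1]
  expect_equal(length(unique(tot)), 1)
  expect_true(all((st$mA + st$mN)[st$type == 2] == 0))
  # per-cell draws vary and have mean near mu
  set.seed(47)
  st <- seed_initial_population(
    seeding_spec(mu = 100, Ng0 = 400, No0 = 0, per_cell_draw = TRUE),
    p_ge, p_o, ge)
  tot <- st$mA + st$mN
  expect_gt(length(unique(tot)), 1)
  expect_lt(abs(mean(tot) - 100), 3 * sqrt(100 / 400))
  # expected mutualist fraction is one half
  expect_lt(abs(mean(st$mA / tot) - 0.5), 0.05)
  # nonautonomous mutualist class stores the mutualist count in mN
  set.seed(48)
  ge_n <- std_ge(mutualist_class = "nonautonomous")
  st_n <- seed_initial_population(
    seeding_spec(mu = 100, Ng0 = 400, No0 = 0, per_cell_draw = TRUE),
    p_ge, p_o, ge_n)
  expect_lt(abs(mean(st_n$mN / (st_n$mA + st_n$mN)) - 0.5), 0.05)
})
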