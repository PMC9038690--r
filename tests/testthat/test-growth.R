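test_that("Monod growth rate has the stated condition structure", {
  p <- test_producer()
  c <- test_consumer()
  # saturation limit and half-saturation point
  expect_equal(growth_rate(p, "oxic", C = 1e9), p$mu_max, tolerance = 1e-6)
  expect_equal(growth_rate(p, "oxic", C = p$K_C), p$mu_max / 2)
  # anoxic hard limitation by the strain's own N acceptor
  expect_equal(growth_rate(p, "anoxic", C = 50, no3 = 0, no2 = 10), 0)
  expect_equal(growth_rate(c, "anoxic", C = 50, no3 = 10, no2 = 0), 0)
  # oxic rate ignores the N species entirely
  expect_equal(growth_rate(c, "oxic", C = 5, no3 = 0, no2 = 0),
               growth_rate(c, "oxic", C = 5, no3 = 9, no2 = 9))
  # anoxic dual-Monod composition
  expect_equal(growth_rate(p, "anoxic", C = 5, no3 = 0.3),
               p$mu_max * 5 / (p$K_C + 5) * 0.3 / (p$K_N + 0.3))
  expect_error(growth_rate(p, "oxic", C = -1), "invalid argument")
})

test_that("growth rate is monotone in each substrate and bounded", {
  p <- test_producer()
  grid <- c(0, 10^seq(-3, 2, length.out = 12))
  for (cond in c("oxic", "anoxic")) {
    mu_c <- growth_rate(p, cond, C = grid, no3 = 0.5)
    expect_true(all(diff(mu_c) >= 0))
    expect_true(all(mu_c >= 0 & mu_c <= p$mu_max))
  }
  mu_n <- growth_rate(p, "anoxic", C = 5, no3 = grid)
  expect_true(all(diff(mu_n) >= 0))
})

test_that("nitrite-inhibited yield follows the two-branch hyperbola", {
  p <- test_producer()
  no2 <- c(0, 0.01, p$K_inh, 1, 50, 1e6)
  # pH 7.5: no toxicity whatever the nitrite level
  expect_equal(yield_coefficient(p, no2, 7.5), rep(p$Y_max, length(no2)))
  # pH 6.5 anchor points
  expect_equal(yield_coefficient(p, 0, 6.5), p$Y_max)
  expect_equal(yield_coefficient(p, p$K_inh, 6.5), (p$Y_max + p$Y_min) / 2)
  expect_equal(yield_coefficient(p, 1e12, 6.5), p$Y_min, tolerance = 1e-9)
  y <- yield_coefficient(p, no2, 6.5)
  expect_true(all(diff(y) <= 0))
  expect_true(all(y >= p$Y_min & y <= p$Y_max))
  # K_inh -> infinity at pH 6.5 reproduces the pH 7.5 branch
  p_noinh <- test_producer(K_inh = 1e15)
  expect_equal(yield_coefficient(p_noinh, no2, 6.5),
               yield_coefficient(p_noinh, no2, 7.5), tolerance = 1e-9)
  expect_error(yield_coefficient(p, -0.1, 6.5), "invalid argument")
})

test_that("Euler update converts units and approaches the exponential", {
  expect_equal(euler_update(2e-13, 0, 60), 2e-13)
  expect_equal(euler_update(1, 0.1, 3600), 1.1)
  # repeated small steps approach exp(mu t) from below
  m <- 1
  for (i in 1:3600) m <- euler_update(m, 0.5, 1)
  expect_lt(m, exp(0.5))
  expect_equal(m, exp(0.5), tolerance = 1e-4)
  expect_error(euler_update(1, -0.1, 60), "invalid argument")
})

test_that("consumption and production respect stoichiometry", {
  lat <- hex_lattice(120, 20)
  f <- nutrient_field(lat, init = c(carbon = 22, no3 = 1, no2 = 0.4),
                      boundary = "none")
  p <- test_producer()
  co <- test_consumer()
  vol <- f$node_volume_L
  dm <- 1e-15
  # producer, anoxic: NO3 down by dm/Yi mol, NO2 up by the same amount
  res <- consume_and_produce(1L, p, dm, f, "anoxic", 6.5)
  Yi <- yield_coefficient(p, 0.4, 6.5)
  expect_equal(unname(res$consumed[["no3"]]), 1000 * dm / Yi)
  expect_equal(unname(res$produced_no2), unname(res$consumed[["no3"]]))
  expect_equal(unname(res$field$conc[1L, "no3"]),
               1 - res$consumed[["no3"]] / vol)
  expect_equal(unname(res$field$conc[1L, "no2"]),
               unname(0.4 + res$produced_no2 / vol))
  expect_equal(unname(res$consumed[["carbon"]]), 1000 * dm / p$Y_carbon)
  expect_false(res$capped)
  # consumer, oxic: only carbon moves
  res2 <- consume_and_produce(2L, co, dm, f, "oxic", 6.5)
  expect_equal(unname(res2$field$conc[2L, "no3"]), 1)
  expect_equal(unname(res2$field$conc[2L, "no2"]), 0.4)
  expect_lt(res2$field$conc[2L, "carbon"], 22)
  # consumer, anoxic: removes nitrite
  res3 <- consume_and_produce(3L, co, 2e-16, f, "anoxic", 7.5)
  expect_equal(unname(res3$consumed[["no2"]]), 1000 * 2e-16 / co$Y_max)
  expect_equal(res3$produced_no2, 0)
})

test_that("growth is capped by local availability, never negative", {
  lat <- hex_lattice(120, 20)
  f <- nutrient_field(lat, init = c(carbon = 22, no3 = 1e-6, no2 = 0),
                      boundary = "none")
  p <- test_producer()
  res <- consume_and_produce(1L, p, 1e-12, f, "anoxic", 7.5)
  expect_true(res$capped)
  expect_lt(res$dbiomass, 1e-12)
  expect_gte(res$field$conc[1L, "no3"], 0)
  expect_equal(unname(res$field$conc[1L, "no3"]), 0, tolerance = 1e-20)
  # nitrogen ledger holds exactly under capping
  expect_equal(unname(res$produced_no2), unname(res$consumed[["no3"]]))
})

test_that("nitrogen ledger is conserved across mixed single-node events", {
  lat <- hex_lattice(120, 20)
  f <- nutrient_field(lat, init = c(carbon = 22, no3 = 1, no2 = 0.2),
                      boundary = "none")
  p <- test_producer(); co <- test_consumer()
  vol <- f$node_volume_L
  n0 <- sum(f$conc[, "no3"] + f$conc[, "no2"]) * vol
  removed <- 0
  set.seed(4)
  for (i in 1:50) {
    node <- sample(lat$n, 1)
    who <- sample(list(p, co), 1)[[1]]
    res <- consume_and_produce(node, who, runif(1, 0, 2e-13), f, "anoxic",
                               sample(c(6.5, 7.5), 1))
    f <- res$field
    removed <- removed + res$consumed[["no2"]]
  }
  n1 <- sum(f$conc[, "no3"] + f$conc[, "no2"]) * vol
  expect_equal(n1 + removed, n0, tolerance = 1e-9)
})
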