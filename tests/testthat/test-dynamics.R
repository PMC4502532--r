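test_that("the Fermi rule is symmetric, sharp at small K, and complementary", {
  expect_equal(fermi_probability(1, 1, 0.1), 0.5)
  expect_equal(fermi_probability(2, 1, 0.1), 1 / (1 + exp(10)))
  expect_equal(fermi_probability(1, 2, 0.1), 1 / (1 + exp(-10)))
  expect_equal(fermi_probability(2, 1, 0.1) + fermi_probability(1, 2, 0.1), 1)
  # strictly decreasing in the imitator's payoff advantage
  gaps <- seq(-2, 2, by = 0.5)
  w <- fermi_probability(1 + gaps, 1, 0.5)
  expect_true(all(diff(w) < 0))
  # a full-group cooperator against a full-group defector converts it almost
  # surely: phi = r = 4 versus phi = 1 at K = 0.1
  expect_equal(fermi_probability(1, 4, 0.1), 1 / (1 + exp(-30)))
})

test_that("imitation cannot create strategies that are absent", {
  pr <- pgg_params(n = 20, s = 5, r = 4)
  st <- pgg_state(rep(0L, 20), rep(1L, 20), rep(1:4, each = 5), pr)
  set.seed(404)
  for (i in 1:50) st <- elementary_step(st)
  expect_identical(st$strategies, rep(0L, 20))
})

test_that("monomorphic populations are absorbing under every rule", {
  for (rule in c("image", "group", "hybrid")) {
    pr <- pgg_params(n = 20, s = 5, r = 4, p = 0.5)
    allC <- pgg_state(rep(1L, 20), rep(1L, 20), rep(1:4, each = 5), pr)
    allD <- pgg_state(rep(0L, 20), rep(1L, 20), rep(1:4, each = 5), pr)
    set.seed(11)
    outC <- monte_carlo_step(allC, pr, rule)
    set.seed(11)
    outD <- monte_carlo_step(allD, pr, rule)
    expect_identical(outC$strategies, allC$strategies)
    expect_identical(outD$strategies, allD$strategies)
    expect_identical(outC$scores, allC$scores)  # ties retain initial scores
  }
})

test_that("the compiled and reference engines are bit-equal under a seed", {
  pr <- pgg_params(n = 20, s = 5, r = 3, p = 0.3)
  set.seed(8)
  st <- init_population(pr, 0.5)
  for (rule in c("image", "group", "hybrid")) {
    set.seed(99)
    a <- monte_carlo_step(st, pr, rule, engine = "cpp")
    set.seed(99)
    b <- monte_carlo_step(st, pr, rule, engine = "R")
    expect_identical(a, b)
  }
  x <- run_pgg(pr, "hybrid", 0.4, mc_steps = 40, realizations = 3,
               seed = 21, record_classes = TRUE, engine = "cpp")
  y <- run_pgg(pr, "hybrid", 0.4, mc_steps = 40, realizations = 3,
               seed = 21, record_classes = TRUE, engine = "R")
  expect_identical(x$trajectories, y$trajectories)
  expect_identical(x$class_fractions, y$class_fractions)
  expect_identical(x$absorbed_at, y$absorbed_at)
})

test_that("the whole pipeline is bit-reproducible from its seed", {
  pr <- pgg_params(n = 50, s = 5, r = 4, p = 1)
  a <- run_pgg(pr, "image", 0.5, mc_steps = 100, realizations = 4, seed = 3)
  b <- run_pgg(pr, "image", 0.5, mc_steps = 100, realizations = 4, seed = 3)
  expect_identical(a$trajectories, b$trajectories)
  expect_identical(a$stationary, b$stationary)
  # and reruns from the config echo reproduce the output exactly
  cfg <- a$config
  c_ <- run_pgg(cfg$params, cfg$rule, cfg$init_coop_fraction, cfg$mc_steps,
                cfg$realizations, cfg$seed,
                measure_window = cfg$measure_window)
  expect_identical(c_$trajectories, a$trajectories)
})

test_that("degenerate run lengths and initial fractions behave exactly", {
  pr <- pgg_params(n = 30, s = 5, r = 2, p = 1)
  z <- run_pgg(pr, "image", 0.4, mc_steps = 0, realizations = 2, seed = 1,
               measure_window = 1)
  expect_identical(dim(z$trajectories), c(2L, 1L))
  expect_equal(unname(z$trajectories[, 1]), c(0.4, 0.4))
  allc <- run_pgg(pr, "image", 1, mc_steps = 20, realizations = 2, seed = 1)
  expect_true(all(allc$trajectories == 1))
  alld <- run_pgg(pr, "image", 0, mc_steps = 20, realizations = 2, seed = 1)
  expect_true(all(alld$trajectories == 0))
  expect_identical(alld$absorbed_at, c(0L, 0L))
  # rounding of the initial cooperator count
  set.seed(2)
  st <- init_population(pgg_params(n = 1500, s = 5, r = 4), 0.5)
  expect_identical(sum(st$strategies), 750L)
})

test_that("stationary_fraction averages the trailing window", {
  expect_equal(stationary_fraction(rep(1, 10), 5), 1)
  expect_equal(stationary_fraction(rep(0, 10), 3), 0)
  expect_equal(stationary_fraction(rep(0.4, 7), 7), 0.4)
  expect_equal(stationary_fraction(c(0, 0, 1, 1), 2), 1)
  expect_error(stationary_fraction(rep(1, 5), 6), "window")
})

test_that("recorded class fractions partition the population", {
  pr <- pgg_params(n = 40, s = 5, r = 3, p = 0.5)
  sim <- run_pgg(pr, "hybrid", 0.5, mc_steps = 30, realizations = 2,
                 seed = 10, record_classes = TRUE)
  sums <- apply(sim$class_fractions, c(1, 2), sum)
  expect_true(all(abs(sums - 1) < 1e-12))
  expect_true(all(sim$class_fractions >= 0))
  # the cooperator fraction is the sum of the two cooperator classes
  coop <- sim$class_fractions[, , "C1"] + sim$class_fractions[, , "C0"]
  expect_equal(unname(coop), unname(sim$trajectories), tolerance = 1e-12)
})
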