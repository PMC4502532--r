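test_that("class states are validated and expose action masses", {
  cs <- class_state(pC1 = 0.7, pD1 = 0.1, pC0 = 0.15, pD0 = 0.05)
  expect_equal(sum(unclass(cs)), 1)
  expect_error(class_state(pC1 = 0.5, pD0 = 0.4), "sum to 1")
  expect_error(class_state(pC1 = 1.2, pD0 = -0.2), "nonnegative")
})

test_that("mean-field class payoffs reproduce the closed-form reference state", {
  pr <- pgg_params(n = 1500, s = 5, r = 4)
  # all groups but one are pure high-score cooperators; the bottom group
  # mixes low-score cooperators and defectors
  cs <- class_state(pC1 = 1495 / 1500, pC0 = 5 / 1500 - 0.001, pD0 = 0.001)
  pi <- expected_class_payoffs(cs, pr)
  expect_equal(pi[["C1"]], 4)                       # pi_C1 = r
  expect_equal(pi[["C0"]], (5 - 1500 * 0.001) * 4 / 5)   # = 2.8
  expect_equal(pi[["D0"]], 1 + (5 - 1500 * 0.001) * 4 / 5)  # = 3.8
  expect_equal(pi[["D0"]] - pi[["C0"]], 1)
  expect_equal(attr(pi, "pi_bar"),
               sum(unclass(cs) * unclass(pi)[1:4]), tolerance = 1e-12)
  # a lone cooperator among defectors earns the marginal per-capita rate
  lone <- class_state(pC1 = 1 / 1500, pD0 = 1499 / 1500)
  expect_equal(expected_class_payoffs(lone, pr)[["C1"]], 4 / 5)
})

test_that("replicator growth rates conserve mass and vanish at monomorphism", {
  pr <- pgg_params(n = 1500, s = 5, r = 4)
  mono <- class_state(pC1 = 1)
  d0 <- replicator_derivative(mono, expected_class_payoffs(mono, pr))
  expect_equal(unname(d0), c(0, 0))
  set.seed(19)
  for (case in 1:10) {
    m <- stats::runif(4)
    m <- m / sum(m)
    cs <- class_state(m[1], m[2], m[3], m[4])
    d <- replicator_derivative(cs, expected_class_payoffs(cs, pr))
    expect_equal(d[["dpC"]] + d[["dpD"]], 0, tolerance = 1e-12)
  }
  # near-universal defection: the rare cooperator class shrinks
  rare <- class_state(pC1 = 1 / 1500, pD0 = 1499 / 1500)
  d <- replicator_derivative(rare, expected_class_payoffs(rare, pr))
  expect_lt(d[["dpC"]], 0)
})

test_that("the interior image-scoring rest point matches the closed form", {
  for (n in c(1500, 150)) for (r in c(1.1, 4)) {
    pr <- pgg_params(n = n, s = 5, r = r)
    root <- stationary_pD0_image(pr)
    expect_equal(root, pD0_closed_form(n, 5, r), tolerance = 1e-10)
    expect_gt(root, 0)
    expect_lt(root, 5 / n)
  }
  # the reference case frozen numerically: n = 1500, s = 5, r = 4 gives 1/1197
  pr <- pgg_params(n = 1500, s = 5, r = 4)
  expect_equal(stationary_pD0_image(pr), 1 / 1197, tolerance = 1e-12)
})

test_that("the rest point is bracketed by opposite-signed growth rates", {
  pr <- pgg_params(n = 1500, s = 5, r = 4)
  root <- stationary_pD0_image(pr)
  dpC_at <- function(x) {
    cs <- class_state(pC1 = 1495 / 1500, pC0 = 5 / 1500 - x, pD0 = x)
    replicator_derivative(cs, expected_class_payoffs(cs, pr))[["dpC"]]
  }
  expect_lt(abs(dpC_at(root)), 1e-10)
  expect_true(dpC_at(root / 2) * dpC_at(2 * root) < 0)
})

test_that("integration preserves mass and respects monomorphic fixed points", {
  pr <- pgg_params(n = 1500, s = 5, r = 4)
  fl <- integrate_replicator(class_state(pD0 = 1), pr, "image", horizon = 20)
  expect_true(all(abs(rowSums(fl$states) - 1) < 1e-9))
  expect_true(all(fl$states >= 0))
  expect_equal(fl$pC, rep(0, 21))
  fl2 <- integrate_replicator(class_state(pC1 = 0.6, pD1 = 0.1, pC0 = 0.1,
                                          pD0 = 0.2), pr, "group",
                              horizon = 50)
  expect_true(all(abs(rowSums(fl2$states) - 1) < 1e-9))
})

test_that("a rare cooperator class is driven out under every scoring rule", {
  for (rule in c("image", "group", "hybrid")) {
    pr <- pgg_params(n = 1500, s = 5, r = 4, p = 0.5)
    start <- class_state(pC1 = 1 / 1500, pD0 = 1499 / 1500)
    fl <- integrate_replicator(start, pr, rule, horizon = 200, dt = 0.1)
    expect_lt(fl$pC[length(fl$pC)], 1e-8)
  }
})

test_that("the high-cooperation state survives probing under image scoring only", {
  pr <- pgg_params(n = 1500, s = 5, r = 4)
  root <- stationary_pD0_image(pr)
  ref <- class_state(pC1 = 1495 / 1500, pC0 = 5 / 1500 - root, pD0 = root)
  probe_i <- stability_probe(ref, pr, "image", epsilon = 1e-4)
  expect_identical(probe_i$verdict, "stable")
  expect_gt(probe_i$pC_final, 4 / 5)
  expect_lte(probe_i$final[["D1"]], 1e-4)
  probe_g <- stability_probe(ref, pr, "group", epsilon = 1e-4)
  expect_identical(probe_g$verdict, "unstable")
  expect_lt(probe_g$pC_final, 4 / 5)
  # no perturbation, no verdict change; invalid perturbations are rejected
  expect_identical(stability_probe(ref, pr, "image", epsilon = 0)$verdict,
                   "stable")
  expect_error(stability_probe(ref, pr, "image", epsilon = -1e-4),
               "nonnegative")
})
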