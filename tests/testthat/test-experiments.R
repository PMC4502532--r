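test_that("the fixture registry builds the documented micro-populations", {
  two <- make_fixture("two_groups_split")
  expect_identical(two$strategies, rep(c(1L, 0L), each = 5))
  expect_identical(two$scores, rep(c(1L, 0L), each = 5))
  lone <- make_fixture("lone_cooperator")
  expect_identical(sum(lone$strategies), 1L)
  expect_identical(lone$scores, rep(1L, 25))
  bnd <- make_fixture("boundary_tie")
  expect_identical(sum(bnd$scores), 7L)
  expect_error(make_fixture("nope"))
})

test_that("the image experiment fixes cooperation and reports its decay", {
  e <- experiment_image(n = 50, mc_steps = 400, realizations = 5, seed = 2)
  expect_true(e$summary$all_fixed_coop)
  expect_true(all(e$sim$stationary == 1))
  expect_lt(e$summary$decay$rate, 0)
  expect_true(is.numeric(e$summary$decay$r_squared))
})

test_that("the group experiment absorbs at defection from both starts", {
  e <- experiment_group(n = 50, r = 1.5, mc_steps = 800, realizations = 5,
                        seed = 2)
  expect_true(e$summary$all_fixed_defect)
  expect_true(all(unlist(e$summary$stationary) == 0))
  # an invader-free cooperative population has nothing to die from
  full <- run_pgg(pgg_params(n = 50, s = 5, r = 1.5, p = 0), "group", 1,
                  mc_steps = 50, realizations = 2, seed = 1)
  expect_true(all(full$trajectories == 1))
})

test_that("phase tables cover every sweep cell with valid summaries", {
  ph <- experiment_hybrid_size(k_grid = c(4, 10), s = 5, r = 1.1, p = 0.01,
                               mc_steps = 300, realizations = 3, seed = 5)
  expect_s3_class(ph, "pgg_phase")
  expect_identical(nrow(ph), 2L)
  expect_identical(ph$n, c(20L, 50L))
  expect_true(all(ph$coop_mean >= 0 & ph$coop_mean <= 1))
  expect_true(all(ph$coop_sd >= 0))
  expect_true(all(ph$survival >= 0 & ph$survival <= 1))
})

test_that("a degenerate single-cell sweep equals a direct simulation run", {
  res <- experiment_hybrid_thresholds(k_grid = 20, r_grid = 2, p_grid = 0.5,
                                      p_fixed = 0.5, r_fixed = 2, s = 5,
                                      mc_steps = 200, realizations = 3,
                                      seed = 9)
  expect_identical(nrow(res$table), 2L)
  direct <- run_pgg(pgg_params(n = 100, s = 5, r = 2, p = 0.5), "hybrid",
                    0.5, mc_steps = 200, realizations = 3, seed = 10)
  expect_equal(res$table$coop_mean[1], mean(direct$stationary))
  expect_true(all(c("critical_r", "critical_p") %in% names(res$critical)))
})

test_that("simulation outputs round-trip through tidy CSV and JSON", {
  sim <- run_pgg(pgg_params(n = 20, s = 5, r = 2, p = 1), "image", 0.5,
                 mc_steps = 10, realizations = 2, seed = 4,
                 record_classes = TRUE)
  csv <- tempfile(fileext = ".csv")
  js <- tempfile(fileext = ".json")
  df <- write_sim_output(sim, csv, js)
  expect_identical(nrow(df), 2L * 11L)
  back <- utils::read.csv(csv)
  expect_equal(back$coop_fraction, df$coop_fraction)
  expect_true(all(c("p_C1", "p_D1", "p_C0", "p_D0") %in% names(back)))
  echo <- jsonlite::read_json(js, simplifyVector = TRUE)
  expect_equal(echo$config$seed, 4)
  # rerunning from the echoed config reproduces the run bit-exactly
  again <- run_pgg(do.call(pgg_params, echo$config$params[c("n", "k", "s", "r", "p", "K")]),
                   echo$config$rule, echo$config$init_coop_fraction,
                   echo$config$mc_steps, echo$config$realizations,
                   echo$config$seed, record_classes = TRUE)
  expect_identical(again$trajectories, sim$trajectories)
})

test_that("image scoring sustains high cooperation across group sizes and returns", {
  # strict fixation at strong synergy; a high-cooperation stationary state
  # with a persistent boundary free-rider minority at weak synergy
  for (s in c(4, 5, 10)) {
    sim <- run_pgg(pgg_params(n = 120, s = s, r = 1.5, p = 1), "image", 0.5,
                   mc_steps = 3000, realizations = 3, seed = 3)
    expect_gt(mean(sim$stationary), 0.7)
  }
  fix <- run_pgg(pgg_params(n = 600, s = 5, r = 4, p = 1), "image", 0.5,
                 mc_steps = 2000, realizations = 3, seed = 3)
  expect_true(all(fix$stationary == 1))
})

test_that("group scoring drives cooperators extinct at weak synergy", {
  for (s in c(4, 5, 10)) {
    sim <- run_pgg(pgg_params(n = 120, s = s, r = 1.5, p = 0), "group", 0.5,
                   mc_steps = 3000, realizations = 3, seed = 3)
    expect_true(all(sim$stationary == 0))
  }
  big <- run_pgg(pgg_params(n = 600, s = 10, r = 4, p = 0), "group", 0.5,
                 mc_steps = 3000, realizations = 3, seed = 3)
  expect_true(all(big$stationary == 0))
})
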