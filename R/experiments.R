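#' Deterministic micro-populations for testing and demonstration
#'
#' A small registry of fully specified population states that exercise the
#' game's corner cases.
#'
#' \describe{
#'   \item{`"two_groups_split"`}{n = 10, s = 5: five cooperators with score 1
#'     in group 1, five defectors with score 0 in group 2.}
#'   \item{`"lone_cooperator"`}{n = 25, s = 5: a single cooperator among 24
#'     defectors, all scores 1.}
#'   \item{`"boundary_tie"`}{n = 10, s = 5: seven score-1 players (the five
#'     cooperators plus two defectors) and three score-0 defectors, so
#'     score-ranked matching must break ties at the group boundary.}
#' }
#'
#' @param name one of the registry names above.
#' @param r,p,K game constants for the embedded [pgg_params()].
#' @return A [pgg_state()].
#' @examples
#' make_fixture("lone_cooperator")
#' @export
make_fixture <- function(name = c("two_groups_split", "lone_cooperator",
                                  "boundary_tie"), r = 4, p = 1, K = 0.1) {
  name <- match.arg(name)
  switch(name,
    two_groups_split = {
      pr <- pgg_params(n = 10, s = 5, r = r, p = p, K = K)
      pgg_state(rep(c(1L, 0L), each = 5L), rep(c(1L, 0L), each = 5L),
                rep(1:2, each = 5L), pr)
    },
    lone_cooperator = {
      pr <- pgg_params(n = 25, s = 5, r = r, p = p, K = K)
      pgg_state(c(1L, rep(0L, 24L)), rep(1L, 25L),
                rep(1:5, each = 5L), pr)
    },
    boundary_tie = {
      pr <- pgg_params(n = 10, s = 5, r = r, p = p, K = K)
      pgg_state(rep(c(1L, 0L), each = 5L),
                c(rep(1L, 7L), rep(0L, 3L)),
                rep(1:2, each = 5L), pr)
    })
}

#' Image-scoring experiment: cooperators rise to dominance
#'
#' Runs the image-scoring ensemble (defaults: `s = 5`, `r = 4`, initial
#' cooperator fraction 0.5) and summarizes fixation together with the fitted
#' exponential decay rate of the ensemble defector fraction. The full-scale
#' population is `n = 1500`; the default here is a desk-scale `n = 150`, and
#' the outcome -- fixation of cooperation -- is independent of `n`, `s`
#' and `r`.
#'
#' @param n,s,r game constants.
#' @param init_coop_fraction initial cooperator fraction.
#' @param mc_steps,realizations,seed ensemble controls.
#' @return List with the `pgg_sim` object (`sim`), a `summary` list (per-
#'   realization stationary fractions, fixation counts, decay fit), and the
#'   `config` echo.
#' @export
experiment_image <- function(n = 150, s = 5, r = 4, init_coop_fraction = 0.5,
                             mc_steps = 2000, realizations = 20, seed = 1) {
  params <- pgg_params(n = n, s = s, r = r, p = 1)
  sim <- run_pgg(params, rule = "image",
                 init_coop_fraction = init_coop_fraction,
                 mc_steps = mc_steps, realizations = realizations, seed = seed)
  decay <- tryCatch(defector_decay_fit(sim), error = function(e) NULL)
  list(sim = sim,
       summary = list(stationary = sim$stationary,
                      all_fixed_coop = all(sim$stationary == 1),
                      decay = decay),
       config = sim$config)
}

#' Group-scoring experiment: cooperators die out
#'
#' Runs the group-scoring ensemble from several initial cooperator fractions
#' (defaults 0.25 and 0.75); under group scoring every realization is expected
#' to absorb at full defection regardless of the starting point. The default
#' horizon is long (3e5 Monte Carlo steps) because at strong synergy
#' (`r/s` close to 1) the population first falls into a defection-dominated
#' quasi-stationary state (cooperator fraction about 0.2) and full extinction
#' is fluctuation-driven, with absorption times of order 1e4--1e5 steps at
#' `n = 150`; absorbed realizations exit early, so the ensemble still runs in
#' about a minute.
#'
#' @param init_fractions initial cooperator fractions to run.
#' @inheritParams experiment_image
#' @return List with one `pgg_sim` per initial fraction (`sims`), a `summary`
#'   list, and the `config` echo.
#' @export
experiment_group <- function(n = 150, s = 5, r = 4,
                             init_fractions = c(0.25, 0.75),
                             mc_steps = 3e5, realizations = 20, seed = 1) {
  params <- pgg_params(n = n, s = s, r = r, p = 0)
  sims <- lapply(seq_along(init_fractions), function(i)
    run_pgg(params, rule = "group", init_coop_fraction = init_fractions[i],
            mc_steps = mc_steps, realizations = realizations,
            seed = seed + i - 1))
  names(sims) <- paste0("init_", init_fractions)
  list(sims = sims,
       summary = list(
         stationary = lapply(sims, `[[`, "stationary"),
         all_fixed_defect = all(vapply(sims, function(s_)
           all(s_$stationary == 0), logical(1)))),
       config = list(n = n, s = s, r = r, init_fractions = init_fractions,
                     mc_steps = mc_steps, realizations = realizations,
                     seed = seed))
}

run_phase_cell <- function(n, s, r, p, init_coop_fraction, mc_steps,
                           realizations, seed) {
  params <- pgg_params(n = n, s = s, r = r, p = p)
  sim <- run_pgg(params, rule = "hybrid",
                 init_coop_fraction = init_coop_fraction,
                 mc_steps = mc_steps, realizations = realizations, seed = seed)
  data.frame(n = params$n, k = params$k, s = params$s, r = r, p = p,
             coop_mean = mean(sim$stationary),
             coop_sd = stats::sd(sim$stationary),
             survival = mean(sim$stationary > 0),
             realizations = realizations, seed = seed)
}

#' Hybrid scoring across population sizes
#'
#' Sweeps the number of groups `k` (hence the population size `n = k s`) at a
#' small image-information rate (defaults `p = 0.01`, `r = 1.1`, `s = 5`).
#' Cooperation survives only when the population is large enough for
#' cooperators to segregate into homogeneous groups before dying out, so the
#' survival frequency rises with `k`.
#'
#' @param k_grid numbers of groups to sweep.
#' @param p image-scoring probability.
#' @inheritParams experiment_image
#' @return A `data.frame` of class `"pgg_phase"`: one row per grid cell with
#'   the stationary cooperator fraction mean/sd, the survival frequency, and
#'   the cell's config.
#' @export
experiment_hybrid_size <- function(k_grid = c(10, 50, 200, 600), s = 5,
                                   r = 1.1, p = 0.01,
                                   init_coop_fraction = 0.5,
                                   mc_steps = 10000, realizations = 10,
                                   seed = 1) {
  rows <- lapply(seq_along(k_grid), function(i)
    run_phase_cell(n = k_grid[i] * s, s = s, r = r, p = p,
                   init_coop_fraction = init_coop_fraction,
                   mc_steps = mc_steps, realizations = realizations,
                   seed = seed + i - 1))
  out <- do.call(rbind, rows)
  class(out) <- c("pgg_phase", "data.frame")
  attr(out, "sweep") <- "k"
  out
}

#' Hybrid scoring thresholds in the rate of return and information rate
#'
#' For each number of groups, sweeps the rate of return `r` at fixed `p`
#' (main sweep) and the information rate `p` at fixed `r` (inset sweep), and
#' estimates the critical value as the first grid point at which the
#' ensemble-mean stationary cooperator fraction exceeds 0.5. Small
#' populations show abrupt drops to full defection below critical `r` and
#' `p`; a necessary lower bound on the information rate is `p >= 2/n`.
#'
#' @param k_grid numbers of groups.
#' @param r_grid rates of return for the main sweep (at `p = p_fixed`).
#' @param p_grid information rates for the inset sweep (at `r = r_fixed`).
#' @param p_fixed,r_fixed the held-fixed values.
#' @inheritParams experiment_image
#' @return List with `table` (a `"pgg_phase"` data frame over both sweeps,
#'   column `sweep` marking `"r"` or `"p"`) and `critical` (per `k`, the
#'   estimated critical `r` and `p`, `NA` when cooperation never prevailed on
#'   the grid).
#' @export
experiment_hybrid_thresholds <- function(k_grid = c(10, 50, 200),
                                         r_grid = c(1.1, 2, 3, 4),
                                         p_grid = c(0.001, 0.01, 0.1, 1),
                                         p_fixed = 0.01, r_fixed = 1.1,
                                         s = 5, init_coop_fraction = 0.5,
                                         mc_steps = 10000, realizations = 10,
                                         seed = 1) {
  cells <- list()
  idx <- 0L
  for (k in k_grid) {
    for (r in r_grid) {
      idx <- idx + 1L
      row <- run_phase_cell(n = k * s, s = s, r = r, p = p_fixed,
                            init_coop_fraction, mc_steps, realizations,
                            seed + idx)
      row$sweep <- "r"
      cells[[idx]] <- row
    }
    for (p in p_grid) {
      idx <- idx + 1L
      row <- run_phase_cell(n = k * s, s = s, r = r_fixed, p = p,
                            init_coop_fraction, mc_steps, realizations,
                            seed + idx)
      row$sweep <- "p"
      cells[[idx]] <- row
    }
  }
  tab <- do.call(rbind, cells)
  class(tab) <- c("pgg_phase", "data.frame")
  critical <- do.call(rbind, lapply(k_grid, function(k) {
    tr <- tab[tab$k == k & tab$sweep == "r", ]
    tp <- tab[tab$k == k & tab$sweep == "p", ]
    crit <- function(d, col) {
      hit <- d[[col]][d$coop_mean > 0.5]
      if (length(hit)) min(hit) else NA_real_
    }
    data.frame(k = k, n = k * s,
               critical_r = crit(tr, "r"), critical_p = crit(tp, "p"))
  }))
  list(table = tab, critical = critical)
}

#' @export
print.pgg_phase <- function(x, ...) {
  cat("stationary cooperation across the parameter grid:\n")
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Write a simulation's tidy trajectory table and summary
#'
#' Writes the per-realization trajectories of a [run_pgg()] result as a tidy
#' CSV (columns `realization`, `period`, `coop_fraction`, and the four class
#' fractions when recorded) and, alongside it, a JSON echo of the full
#' configuration plus the stationary summary, so any run can be reproduced
#' bit-exactly from its own output.
#'
#' @param sim a `pgg_sim`.
#' @param csv_path,json_path output paths (either may be `NULL` to skip).
#' @return Invisibly, the tidy data frame.
#' @export
write_sim_output <- function(sim, csv_path = NULL, json_path = NULL) {
  np <- ncol(sim$trajectories)
  m <- nrow(sim$trajectories)
  df <- data.frame(
    realization = rep(seq_len(m), each = np),
    period = rep(seq_len(np) - 1L, times = m),
    coop_fraction = as.vector(t(sim$trajectories)))
  if (!is.null(sim$class_fractions))
    for (cl in dimnames(sim$class_fractions)[[3]])
      df[[paste0("p_", cl)]] <- as.vector(t(sim$class_fractions[, , cl]))
  if (!is.null(csv_path)) utils::write.csv(df, csv_path, row.names = FALSE)
  if (!is.null(json_path)) {
    cfg <- sim$config
    cfg$params <- unclass(cfg$params)
    jsonlite::write_json(
      list(config = cfg,
           stationary_mean = mean(sim$stationary),
           stationary_sd = stats::sd(sim$stationary),
           stationary = sim$stationary),
      json_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(df)
}
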