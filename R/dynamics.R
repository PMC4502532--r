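#' Fermi imitation probability
#'
#' Probability that player `j` adopts player `i`'s strategy after comparing
#' payoffs: `1 / (1 + exp((phi_j - phi_i) / K))`. It equals 1/2 at payoff
#' equality, is strictly decreasing in `phi_j - phi_i`, and `K` sets how
#' noisy imitation is (small `K`: nearly deterministic copying of the higher
#' earner).
#'
#' @param phi_j payoff of the imitating player.
#' @param phi_i payoff of the imitated player.
#' @param K noise parameter (positive).
#' @return Adoption probability in `(0, 1)`.
#' @examples
#' fermi_probability(1, 1, 0.1)       # 0.5
#' fermi_probability(2, 1, 0.1)       # ~4.5e-5: rarely copy a worse earner
#' @export
fermi_probability <- function(phi_j, phi_i, K) {
  stopifnot(all(K > 0))
  1 / (1 + exp((phi_j - phi_i) / K))
}

# pure-R mirror of the compiled sweep; consumes the RNG stream identically
# (three uniforms per elementary step) so the two engines are bit-equal.
imitation_sweep_r <- function(strategies, groups, r, s, K) {
  n <- length(strategies)
  strat <- strategies
  k <- n %/% s
  pot <- as.numeric(tabulate(groups[strat == 1L], nbins = k))
  rs <- r / s
  for (step in seq_len(n)) {
    u <- stats::runif(3L)
    i <- min(floor(u[1L] * n), n - 1) + 1L
    j <- min(floor(u[2L] * (n - 1)), n - 2) + 1L
    if (j >= i) j <- j + 1L
    phi_i <- (1 - strat[i]) + rs * pot[groups[i]]
    phi_j <- (1 - strat[j]) + rs * pot[groups[j]]
    w <- 1 / (1 + exp((phi_j - phi_i) / K))
    if (u[3L] < w && strat[j] != strat[i]) {
      pot[groups[j]] <- pot[groups[j]] + (strat[i] - strat[j])
      strat[j] <- strat[i]
    }
  }
  strat
}

#' One elementary imitation step
#'
#' Draws an ordered pair of distinct players `(i, j)` uniformly from the whole
#' population, computes their payoffs in their current groups, and overwrites
#' `j`'s strategy with `i`'s with the Fermi probability. Scores and groups are
#' untouched. Exposed mainly for inspection and testing; simulations run whole
#' sweeps at once.
#'
#' @param state a [pgg_state()].
#' @param params a [pgg_params()]; defaults to the state's own.
#' @return The updated `pgg_state`.
#' @export
elementary_step <- function(state, params = state$params) {
  n <- params$n
  u <- stats::runif(3L)
  i <- min(floor(u[1L] * n), n - 1) + 1L
  j <- min(floor(u[2L] * (n - 1)), n - 2) + 1L
  if (j >= i) j <- j + 1L
  phi <- compute_payoffs(state, params)
  w <- fermi_probability(phi[j], phi[i], params$K)
  if (u[3L] < w) state$strategies[j] <- state$strategies[i]
  state
}

#' One full Monte Carlo step (one game period)
#'
#' Performs `n` elementary imitation steps (so every player revises once on
#' average), then closes the period: contributions are recorded (equal to the
#' strategies), scores are refreshed by the chosen rule, and groups are
#' re-formed by score ranking.
#'
#' @param state a [pgg_state()].
#' @param params a [pgg_params()]; defaults to the state's own.
#' @param rule scoring rule: `"image"`, `"group"` or `"hybrid"` (hybrid uses
#'   `params$p`).
#' @param engine `"cpp"` (compiled sweep, the default) or `"R"` (reference
#'   implementation); both consume the RNG stream identically and give
#'   bit-equal results under the same seed.
#' @return The next period's `pgg_state`.
#' @export
monte_carlo_step <- function(state, params = state$params,
                             rule = c("hybrid", "image", "group"),
                             engine = c("cpp", "R")) {
  rule <- match.arg(rule)
  engine <- match.arg(engine)
  strat <- if (engine == "cpp")
    imitation_sweep_cpp(state$strategies, state$groups,
                        params$r, params$s, params$K)
  else
    imitation_sweep_r(state$strategies, state$groups,
                      params$r, params$s, params$K)
  p_eff <- switch(rule, image = 1, group = 0, hybrid = params$p)
  scores <- hybrid_score_update(strat, state$groups, state$scores, p_eff)
  groups <- match_by_score(scores, params)
  state$strategies <- strat
  state$scores <- as.integer(scores)
  state$groups <- groups
  state
}

#' Initial population
#'
#' Places exactly `round(n * init_coop_fraction)` cooperators uniformly at
#' random, assigns initial scores, and forms the first matching by score
#' ranking (uniformly random when all initial scores tie, so no strategy
#' information leaks through the initial grouping).
#'
#' @param params a [pgg_params()].
#' @param init_coop_fraction initial cooperator fraction in `[0, 1]`.
#' @param init_scores `"one"` (default: everyone starts with score 1),
#'   `"zero"`, or `"bernoulli"` with success probability `q`.
#' @param q Bernoulli score probability when `init_scores = "bernoulli"`.
#' @return A [pgg_state()].
#' @export
init_population <- function(params, init_coop_fraction = 0.5,
                            init_scores = c("one", "zero", "bernoulli"),
                            q = 0.5) {
  init_scores <- match.arg(init_scores)
  stopifnot(init_coop_fraction >= 0, init_coop_fraction <= 1)
  n <- params$n
  strat <- integer(n)
  nc <- as.integer(round(n * init_coop_fraction))
  if (nc > 0L) strat[sample.int(n, nc)] <- 1L
  scores <- switch(init_scores,
                   one = rep(1L, n),
                   zero = rep(0L, n),
                   bernoulli = as.integer(stats::runif(n) < q))
  groups <- match_by_score(scores, params)
  pgg_state(strat, scores, groups, params)
}

#' Run the evolutionary simulation
#'
#' Runs `realizations` independent Monte Carlo histories of `mc_steps` full
#' steps each, recording the cooperator fraction (and optionally the four
#' action-score class fractions) after every step. Both monomorphic states
#' are absorbing -- there is no mutation -- so a realization that reaches
#' all-cooperate or all-defect is finished early and padded with the absorbed
#' value, which changes nothing recorded.
#'
#' Time is organized in game periods: each period consists of
#' `events_per_period` elementary imitation events, after which every
#' player's score is refreshed and all groups are re-formed by score ranking.
#' One full Monte Carlo step spans `n` elementary events. The default
#' (`events_per_period = n`) makes one period coincide with one Monte Carlo
#' step; `events_per_period = 1` is the opposite extreme in which reputations
#' and matching react to every single strategy revision (much slower, as
#' every event triggers a full rescore and rematch).
#'
#' @param params a [pgg_params()].
#' @param rule scoring rule: `"image"`, `"group"` or `"hybrid"`.
#' @param init_coop_fraction initial cooperator fraction.
#' @param mc_steps number of full Monte Carlo steps per realization.
#' @param realizations number of independent runs.
#' @param seed integer seed; the whole ensemble is bit-reproducible from it.
#' @param measure_window trailing number of steps averaged for the stationary
#'   estimate (default: final 10% of `mc_steps`, at least 1).
#' @param record_classes also record per-step fractions of the four
#'   action-score classes (C1, D1, C0, D0).
#' @param init_scores,q passed to [init_population()].
#' @param events_per_period imitation events between consecutive
#'   rescore-and-rematch updates (default `n`, one period per Monte Carlo
#'   step).
#' @param engine `"cpp"` (compiled, the default) or `"R"` (reference mirror);
#'   bit-equal under the same seed.
#' @return An object of class `"pgg_sim"`: list with `trajectories` (a
#'   `realizations x (mc_steps + 1)` matrix of cooperator fractions, period 0
#'   first), `mean_trajectory`, `stationary` (per-realization stationary
#'   fractions), `absorbed_at` (step of absorption or `NA`), optional
#'   `class_fractions` (array realization x period x class), and a `config`
#'   echo of every argument.
#' @examples
#' pr <- pgg_params(n = 50, s = 5, r = 4, p = 1)
#' sim <- run_pgg(pr, rule = "image", mc_steps = 200, realizations = 3,
#'                seed = 42)
#' summary(sim)
#' @export
run_pgg <- function(params, rule = c("hybrid", "image", "group"),
                    init_coop_fraction = 0.5, mc_steps = 2000L,
                    realizations = 20L, seed = 1L,
                    measure_window = NULL, record_classes = FALSE,
                    init_scores = "one", q = 0.5,
                    events_per_period = NULL,
                    engine = c("cpp", "R")) {
  rule <- match.arg(rule)
  engine <- match.arg(engine)
  stopifnot(mc_steps >= 0, realizations >= 1)
  n <- params$n
  if (is.null(events_per_period)) events_per_period <- n
  events_per_period <- as.integer(events_per_period)
  stopifnot(events_per_period >= 1)
  if (is.null(measure_window))
    measure_window <- max(1L, as.integer(round(0.1 * mc_steps)))
  if (measure_window > mc_steps + 1L)
    stop("measure_window exceeds the trajectory length", call. = FALSE)
  set.seed(as.integer(seed))
  p_eff <- switch(rule, image = 1, group = 0, hybrid = params$p)
  np <- mc_steps + 1L
  traj <- matrix(NA_real_, nrow = realizations, ncol = np)
  cls <- if (record_classes)
    array(NA_real_, dim = c(realizations, np, 4L),
          dimnames = list(NULL, NULL, c("C1", "D1", "C0", "D0")))
  absorbed_at <- rep(NA_integer_, realizations)

  runner <- if (engine == "cpp") simulate_run_cpp else simulate_run_r
  for (m in seq_len(realizations)) {
    st <- init_population(params, init_coop_fraction, init_scores, q)
    out <- runner(st$strategies, st$scores, st$groups,
                  params$k, params$s, params$r, params$K, p_eff,
                  as.integer(mc_steps), events_per_period, record_classes)
    traj[m, ] <- out$trajectory
    if (record_classes) cls[m, , ] <- out$class_fractions
    if (out$absorbed_at >= 0) absorbed_at[m] <- out$absorbed_at
  }

  stat <- apply(traj, 1L, function(x) mean(x[(np - measure_window + 1L):np]))
  structure(list(
    trajectories = traj,
    mean_trajectory = colMeans(traj),
    stationary = stat,
    absorbed_at = absorbed_at,
    class_fractions = cls,
    config = list(params = params, rule = rule,
                  init_coop_fraction = init_coop_fraction,
                  mc_steps = as.integer(mc_steps),
                  realizations = as.integer(realizations),
                  seed = as.integer(seed),
                  measure_window = as.integer(measure_window),
                  record_classes = record_classes,
                  init_scores = init_scores, q = q,
                  events_per_period = events_per_period, engine = engine)),
    class = "pgg_sim")
}

# pure-R mirror of simulate_run_cpp, consuming the RNG stream identically;
# used to validate the compiled engine on small populations.
simulate_run_r <- function(strategies0, scores0, groups0, k, s, r, K,
                           p_image, mc_steps, events_per_period,
                           record_classes) {
  n <- k * s
  strat <- as.integer(strategies0)
  score <- as.integer(scores0)
  grp <- as.integer(groups0)
  pot <- as.numeric(tabulate(grp[strat == 1L], nbins = k))
  totC <- sum(strat)
  rs <- r / s
  traj <- numeric(mc_steps + 1L)
  traj[1L] <- totC / n
  cls <- if (record_classes) matrix(NA_real_, mc_steps + 1L, 4L)
  rec <- function(row) {
    cls[row, ] <<- c(sum(strat == 1L & score == 1L),
                     sum(strat == 0L & score == 1L),
                     sum(strat == 1L & score == 0L),
                     sum(strat == 0L & score == 0L)) / n
  }
  if (record_classes) rec(1L)
  absorbed_at <- -1L
  since <- 0L
  for (step in seq_len(mc_steps)) {
    if (totC == 0L || totC == n) {
      if (absorbed_at < 0L) absorbed_at <- step - 1L
      traj[(step + 1L):(mc_steps + 1L)] <- traj[step]
      if (record_classes)
        cls[(step + 1L):(mc_steps + 1L), ] <-
          matrix(cls[step, ], mc_steps + 1L - step, 4L, byrow = TRUE)
      break
    }
    for (ev in seq_len(n)) {
      u <- stats::runif(3L)
      i <- min(floor(u[1L] * n), n - 1) + 1L
      j <- min(floor(u[2L] * (n - 1)), n - 2) + 1L
      if (j >= i) j <- j + 1L
      phi_i <- (1 - strat[i]) + rs * pot[grp[i]]
      phi_j <- (1 - strat[j]) + rs * pot[grp[j]]
      w <- 1 / (1 + exp((phi_j - phi_i) / K))
      if (u[3L] < w && strat[j] != strat[i]) {
        pot[grp[j]] <- pot[grp[j]] + (strat[i] - strat[j])
        totC <- totC + (strat[i] - strat[j])
        strat[j] <- strat[i]
      }
      since <- since + 1L
      if (since == events_per_period) {
        since <- 0L
        cbar <- totC / n
        img <- ifelse(strat > cbar, 1L, ifelse(strat < cbar, 0L, score))
        gt <- pot[grp]
        gsc <- ifelse(gt > cbar, 1L, ifelse(gt < cbar, 0L, score))
        score <- if (p_image >= 1) img else if (p_image <= 0) gsc
                 else ifelse(stats::runif(n) < p_image, img, gsc)
        ord <- order(-score, stats::runif(n))
        grp[ord] <- rep(seq_len(k), each = s)
        pot <- as.numeric(tabulate(grp[strat == 1L], nbins = k))
      }
      if (totC == 0L || totC == n) break
    }
    traj[step + 1L] <- totC / n
    if (record_classes) rec(step + 1L)
    if ((totC == 0L || totC == n) && absorbed_at < 0L)
      absorbed_at <- step
  }
  list(trajectory = traj, class_fractions = cls,
       strategies = strat, scores = score, groups = grp,
       absorbed_at = absorbed_at)
}

class_fractions_of <- function(state) {
  n <- length(state$strategies)
  c(C1 = sum(state$strategies == 1L & state$scores == 1L),
    D1 = sum(state$strategies == 0L & state$scores == 1L),
    C0 = sum(state$strategies == 1L & state$scores == 0L),
    D0 = sum(state$strategies == 0L & state$scores == 0L)) / n
}

#' Stationary cooperator fraction of a trajectory
#'
#' Mean cooperator fraction over the trailing `window` recorded periods; for
#' an absorbed run this is exactly the absorbed value.
#'
#' @param trajectory numeric vector of per-period cooperator fractions.
#' @param window number of trailing periods to average (at most the
#'   trajectory length).
#' @export
stationary_fraction <- function(trajectory, window) {
  np <- length(trajectory)
  if (window < 1 || window > np)
    stop("window must lie in [1, length(trajectory)]", call. = FALSE)
  mean(trajectory[(np - window + 1L):np])
}

#' @export
print.pgg_sim <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("pgg_sim: %s scoring, %d realizations x %d MC steps\n",
              cfg$rule, cfg$realizations, cfg$mc_steps))
  print(cfg$params)
  cat(sprintf("  stationary cooperator fraction: mean %.4f, sd %.4f\n",
              mean(x$stationary), stats::sd(x$stationary)))
  invisible(x)
}

#' @export
summary.pgg_sim <- function(object, ...) {
  stat <- object$stationary
  abs_at <- object$absorbed_at
  out <- list(
    rule = object$config$rule,
    params = object$config$params,
    realizations = object$config$realizations,
    mc_steps = object$config$mc_steps,
    stationary_mean = mean(stat),
    stationary_sd = stats::sd(stat),
    n_fixed_coop = sum(stat == 1),
    n_fixed_defect = sum(stat == 0),
    median_absorption_step = stats::median(abs_at, na.rm = TRUE))
  class(out) <- "summary.pgg_sim"
  out
}

#' @export
print.summary.pgg_sim <- function(x, ...) {
  cat(sprintf("%s scoring (n = %d, s = %d, r = %g, p = %g):\n",
              x$rule, x$params$n, x$params$s, x$params$r, x$params$p))
  cat(sprintf("  stationary cooperator fraction %.4f +/- %.4f over %d realizations\n",
              x$stationary_mean, x$stationary_sd, x$realizations))
  cat(sprintf("  fixed at cooperation: %d, fixed at defection: %d (median absorption step %s)\n",
              x$n_fixed_coop, x$n_fixed_defect,
              format(x$median_absorption_step)))
  invisible(x)
}

#' @export
plot.pgg_sim <- function(x, log_defectors = FALSE, ...) {
  t <- seq_len(ncol(x$trajectories)) - 1L
  if (log_defectors) {
    d <- 1 - x$mean_trajectory
    keep <- d > 0
    graphics::plot(t[keep], d[keep], log = "y", type = "l",
                   xlab = "Monte Carlo step",
                   ylab = "ensemble defector fraction", ...)
  } else {
    graphics::matplot(t, t(x$trajectories), type = "l", lty = 1,
                      col = grDevices::adjustcolor("grey40", 0.4),
                      xlab = "Monte Carlo step",
                      ylab = "cooperator fraction", ylim = c(0, 1), ...)
    graphics::lines(t, x$mean_trajectory, lwd = 2)
  }
  invisible(x)
}

#' Exponential decay fit of the ensemble defector fraction
#'
#' Under image scoring defectors vanish exponentially fast once the
#' population has segregated. This fits `log(defector fraction) ~ period`
#' over the selection-driven decay range: from the end of the initial
#' transient (the first period at which the ensemble defector fraction has
#' fallen to `1/e` of its starting value) down to the last period with at
#' least one group's worth of defectors per population (`s/n`). Below that
#' floor the surviving defectors necessarily sit in the mixed boundary group,
#' where they free-ride at a payoff above `r` and are eliminated by imitation
#' noise rather than selection, so that regime is excluded. If the
#' selection-driven range is shorter than four periods (small populations hit
#' the `s/n` floor almost immediately) the fit falls back to the whole
#' positive post-transient range.
#'
#' @param sim a [run_pgg()] result.
#' @return List with `rate` (slope per Monte Carlo step, negative when
#'   decaying), `r_squared`, the fitted range `periods`, and `regime`
#'   (`"selection"` or `"full"` for the fallback).
#' @export
defector_decay_fit <- function(sim) {
  d <- 1 - sim$mean_trajectory
  prm <- sim$config$params
  t <- seq_along(d) - 1L
  start <- which(d <= d[1L] / exp(1))[1L]
  if (is.na(start)) start <- which.max(d)
  stop_sel <- max(which(d >= prm$s / prm$n))
  keep <- seq(start, max(start, stop_sel))
  keep <- keep[d[keep] > 0]
  regime <- "selection"
  if (length(keep) < 4L) {
    keep <- seq(start, max(which(d > 0)))
    keep <- keep[d[keep] > 0]
    regime <- "full"
  }
  if (length(keep) < 3L)
    stop("too few decaying periods to fit", call. = FALSE)
  fit <- stats::lm(log(d[keep]) ~ t[keep])
  list(rate = unname(stats::coef(fit)[2L]),
       r_squared = summary(fit)$r.squared,
       periods = range(t[keep]),
       regime = regime)
}
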