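#' Four-class mean-field state
#'
#' The stability analysis tracks the population masses of the four
#' action-score classes: cooperate-with-score-1 (C1), defect-1 (D1),
#' cooperate-0 (C0) and defect-0 (D0). Actions are hardwired; scores change
#' through the scoring rules. Masses must be nonnegative and sum to one.
#'
#' @param pC1,pD1,pC0,pD0 nonnegative class masses summing to 1.
#' @return Object of class `"pgg_class_state"`: named numeric vector
#'   `c(C1, D1, C0, D0)` with derived attributes `pC` and `pD`.
#' @examples
#' class_state(pC1 = 0.99, pD0 = 0.01)
#' @export
class_state <- function(pC1 = 0, pD1 = 0, pC0 = 0, pD0 = 0) {
  x <- c(C1 = pC1, D1 = pD1, C0 = pC0, D0 = pD0)
  if (any(x < -1e-12))
    stop("class masses must be nonnegative", call. = FALSE)
  x <- pmax(x, 0)
  if (abs(sum(x) - 1) > 1e-9)
    stop(sprintf("class masses must sum to 1 (got %.12f)", sum(x)),
         call. = FALSE)
  structure(x, class = "pgg_class_state")
}

#' @export
print.pgg_class_state <- function(x, ...) {
  cat("action-score class masses:\n")
  print(unclass(x))
  cat(sprintf("  cooperators p_C = %.6f, defectors p_D = %.6f\n",
              x[["C1"]] + x[["C0"]], x[["D1"]] + x[["D0"]]))
  invisible(x)
}

# Expected period payoff of a focal player of class (action a, score sigma)
# under score-ranked matching, given real-valued class head-counts N
# (names C1, D1, C0, D0; sum n). Score-1 players fill the top groups, score-0
# players the bottom groups, with at most one mixed boundary group.
#
# Two regimes, agreeing wherever both apply:
# - class count >= 1 (a discrete member): within a stratum, slots are
#   exchangeable, so group co-membership is a without-replacement draw and
#   the expected number of cooperating group-mates is hypergeometric-linear
#   with the focal excluded from the mate pool. This is the exact
#   expectation of the stochastic matcher for integer counts.
# - class count < 1 (a continuum sliver, as along the replicator flow): the
#   focal is measure-zero inside its stratum, so its group's expected total
#   is just the stratum composition times s and no self-exclusion applies.
#   This limit reproduces the reference closed forms pi_C0 = (s - n pD0) r/s
#   and pi_D0 = 1 + (s - n pD0) r/s at arbitrary sub-unit masses.
focal_payoff <- function(a, sigma, N, params) {
  s <- params$s
  r <- params$r
  cls <- paste0(a, sigma)
  c_self <- as.numeric(a == "C")
  n1 <- N[["C1"]] + N[["D1"]]
  n0 <- N[["C0"]] + N[["D0"]]
  if (N[[cls]] >= 1) {                # discrete member of its stratum
    env <- N
    env[[cls]] <- env[[cls]] - 1
    env1 <- env[["C1"]] + env[["D1"]]
    env0 <- env[["C0"]] + env[["D0"]]
    f1 <- if (env1 > 0) env[["C1"]] / env1 else 0  # coop rate, other score-1
    f0 <- if (env0 > 0) env[["C0"]] / env0 else 0
    b <- n1 %% s                      # score-1 heads in the boundary group
    if (sigma == 1) {
      p_bnd <- if (n1 > 0) b / n1 else 0
      e_pure <- (s - 1) * f1
      e_bnd <- max(b - 1, 0) * f1 + (s - b) * f0
    } else {
      p_bnd <- if (b > 0 && n0 > 0) (s - b) / n0 else 0
      e_pure <- (s - 1) * f0
      e_bnd <- max(s - b - 1, 0) * f0 + b * f1
    }
    e_mates <- (1 - p_bnd) * e_pure + p_bnd * e_bnd
    return((1 - c_self) + (r / s) * (c_self + e_mates))
  }
  # continuum sliver
  f1 <- if (n1 > 0) N[["C1"]] / n1 else 0
  f0 <- if (n0 > 0) N[["C0"]] / n0 else 0
  own_stratum <- if (sigma == 1) n1 else n0
  if (own_stratum < 1e-12) {
    # an invader into an empty stratum forms the boundary group itself,
    # playing with s - 1 members of the other stratum
    f_other <- if (sigma == 1) f0 else f1
    return((1 - c_self) + (r / s) * (c_self + (s - 1) * f_other))
  }
  b <- n1 %% s
  if (sigma == 1) {
    p_bnd <- b / n1
    e_pure <- s * f1
    e_bnd <- b * f1 + (s - b) * f0
  } else {
    p_bnd <- if (b > 0) (s - b) / n0 else 0
    e_pure <- s * f0
    e_bnd <- b * f1 + (s - b) * f0
  }
  e_total <- (1 - p_bnd) * e_pure + p_bnd * e_bnd
  (1 - c_self) + (r / s) * e_total
}

#' Expected class payoffs under score-assorted matching
#'
#' Mean-field expectation of each class's period payoff when score-1 players
#' fill the top groups and score-0 players the bottom groups, with a single
#' mixed boundary group whose composition follows the hypergeometric
#' expectation of the random tie-breaking matcher. At the reference
#' high-cooperation state (`pC1 = (n-s)/n`, `pD1 = 0`) this reproduces the
#' closed forms `pi_C1 = r`, `pi_C0 = (s - n pD0) r/s` and
#' `pi_D0 = 1 + (s - n pD0) r/s`.
#'
#' @param cs a [class_state()].
#' @param params a [pgg_params()] (supplies `n`, `s`, `r`).
#' @return Object of class `"pgg_class_payoffs"`: named vector
#'   `c(C1, D1, C0, D0)` with attribute `pi_bar`, the mass-weighted average.
#' @examples
#' pr <- pgg_params(n = 1500, s = 5, r = 4)
#' cs <- class_state(pC1 = (1500 - 5)/1500, pC0 = 5/1500 - 0.001, pD0 = 0.001)
#' expected_class_payoffs(cs, pr)
#' @export
expected_class_payoffs <- function(cs, params) {
  N <- unclass(cs) * params$n
  pi <- c(C1 = focal_payoff("C", 1, N, params),
          D1 = focal_payoff("D", 1, N, params),
          C0 = focal_payoff("C", 0, N, params),
          D0 = focal_payoff("D", 0, N, params))
  structure(pi, pi_bar = sum(unclass(cs) * pi), class = "pgg_class_payoffs")
}

#' @export
print.pgg_class_payoffs <- function(x, ...) {
  cat("expected class payoffs:\n")
  print(unclass(x)[1:4])
  cat(sprintf("  population average pi_bar = %.6f\n", attr(x, "pi_bar")))
  invisible(x)
}

#' Replicator growth rates of the two actions
#'
#' Each action-score class grows in proportion to its payoff excess over the
#' population average; aggregating over scores gives the growth of each
#' action:
#' \deqn{\partial p_a / \partial t = \sum_{\sigma} p_{a\sigma}
#'       (\pi_{a\sigma} - \bar\pi), \qquad a \in \{C, D\}.}
#' The two rates sum to zero (mass conservation).
#'
#' @param cs a [class_state()].
#' @param payoffs an [expected_class_payoffs()] result for the same state.
#' @return Named numeric vector `c(dpC, dpD)`.
#' @export
replicator_derivative <- function(cs, payoffs) {
  pibar <- attr(payoffs, "pi_bar")
  g <- unclass(cs) * (unclass(payoffs)[1:4] - pibar)
  c(dpC = g[["C1"]] + g[["C0"]], dpD = g[["D1"]] + g[["D0"]])
}

# reference high-cooperation composition of the image-scoring analysis
reference_state <- function(params, pD0) {
  n <- params$n
  s <- params$s
  class_state(pC1 = (n - s) / n, pD1 = 0, pC0 = s / n - pD0, pD0 = pD0)
}

#' Interior rest point of cooperation under image scoring
#'
#' Along the one-parameter family of states with `pC1 = (n-s)/n`, `pD1 = 0`
#' and `pC0 + pD0 = s/n` (all but one group purely high-score cooperators, one
#' bottom group mixing low-score cooperators and defectors), the cooperator
#' growth rate vanishes at a unique `pD0*` in `(0, s/n)`. At that root the
#' total cooperation level `1 - pD0*` exceeds `(s-1)/s`, which is the sense in
#' which image scoring stabilizes high cooperation. Found by bisection on the
#' mean-field growth rate to machine precision.
#'
#' @param params a [pgg_params()] with `r > 1`.
#' @return The root `pD0*` (a single number in `(0, s/n)`).
#' @examples
#' stationary_pD0_image(pgg_params(n = 1500, s = 5, r = 4))  # 1/1197
#' @export
stationary_pD0_image <- function(params) {
  s <- params$s
  n <- params$n
  dpC <- function(x) {
    cs <- reference_state(params, x)
    replicator_derivative(cs, expected_class_payoffs(cs, params))[["dpC"]]
  }
  eps <- 1e-14
  lo <- eps
  hi <- s / n - eps
  flo <- dpC(lo)
  fhi <- dpC(hi)
  if (sign(flo) == sign(fhi))
    stop("no interior root of the cooperator growth rate in (0, s/n); requires r > 1",
         call. = FALSE)
  for (it in 1:200) {
    mid <- (lo + hi) / 2
    fm <- dpC(mid)
    if (fm == 0) return(mid)
    if (sign(fm) == sign(flo)) { lo <- mid; flo <- fm } else hi <- mid
    if (hi - lo < 1e-16) break
  }
  (lo + hi) / 2
}

# Mean-field score-transition map of one period, per rule. Returns the new
# class-state after every player's score is refreshed.
#
# Image scoring: with actions hardwired and contributions binary, any mixed
# state has 0 < mean contribution < 1, so every cooperator scores 1 and every
# defector 0; in a monomorphic state everyone ties the average and scores are
# retained.
#
# Group scoring: at the expectation level, a stratum's groups share the
# expected total contribution (pure score-1 groups, the boundary group, pure
# score-0 groups); all members of a stratum whose expected total exceeds the
# overall average contribution score 1, below it 0, ties retain. Score-1
# defectors in cooperator-rich strata therefore keep their score.
score_transition <- function(cs, params, rule, p = params$p) {
  p_eff <- switch(rule, image = 1, group = 0, hybrid = p)
  img <- if (p_eff > 0) transition_image(cs) else NULL
  grp <- if (p_eff < 1) transition_group(cs, params) else NULL
  if (p_eff == 1) return(img)
  if (p_eff == 0) return(grp)
  class_state(pC1 = p_eff * img[["C1"]] + (1 - p_eff) * grp[["C1"]],
              pD1 = p_eff * img[["D1"]] + (1 - p_eff) * grp[["D1"]],
              pC0 = p_eff * img[["C0"]] + (1 - p_eff) * grp[["C0"]],
              pD0 = p_eff * img[["D0"]] + (1 - p_eff) * grp[["D0"]])
}

transition_image <- function(cs) {
  pC <- cs[["C1"]] + cs[["C0"]]
  if (pC == 0 || pC == 1) return(cs)    # everyone ties the average
  class_state(pC1 = pC, pD1 = 0, pC0 = 0, pD0 = 1 - pC)
}

transition_group <- function(cs, params) {
  s <- params$s
  n <- params$n
  N <- unclass(cs) * n
  n1 <- N[["C1"]] + N[["D1"]]
  n0 <- N[["C0"]] + N[["D0"]]
  f1 <- if (n1 > 0) N[["C1"]] / n1 else 0
  f0 <- if (n0 > 0) N[["C0"]] / n0 else 0
  b <- n1 %% s                           # boundary-group score-1 heads
  tbar <- cs[["C1"]] + cs[["C0"]]        # overall average contribution
  t_pure1 <- s * f1
  t_bnd <- b * f1 + (s - b) * f0
  t_pure0 <- s * f0
  # stratum occupancies (heads), score-1 then score-0 side of the boundary
  occ1_pure <- n1 - b
  occ1_bnd <- b
  occ0_bnd <- if (b > 0) s - b else 0
  occ0_pure <- n0 - occ0_bnd
  new_score <- function(total, current) {
    if (total > tbar + 1e-15) 1 else if (total < tbar - 1e-15) 0 else current
  }
  out <- c(C1 = 0, D1 = 0, C0 = 0, D0 = 0)
  place <- function(out, action, heads, total, current_score) {
    if (heads <= 0) return(out)
    sc <- new_score(total, current_score)
    cls <- paste0(action, sc)
    out[[cls]] <- out[[cls]] + heads / n
    out
  }
  # score-1 stratum members split between pure-1 groups and the boundary
  for (a in c("C", "D")) {
    heads <- N[[paste0(a, "1")]]
    if (heads > 0 && n1 > 0) {
      out <- place(out, a, heads * occ1_pure / n1, t_pure1, 1)
      out <- place(out, a, heads * occ1_bnd / n1, t_bnd, 1)
    }
    heads <- N[[paste0(a, "0")]]
    if (heads > 0 && n0 > 0) {
      out <- place(out, a, heads * occ0_pure / n0, t_pure0, 0)
      out <- place(out, a, heads * occ0_bnd / n0, t_bnd, 0)
    }
  }
  class_state(pC1 = out[["C1"]], pD1 = out[["D1"]],
              pC0 = out[["C0"]], pD0 = out[["D0"]])
}

#' Integrate the coupled replicator / score dynamics
#'
#' Forward integration of the four-class mean field: within each unit of time
#' the class masses follow the replicator flow (Euler substeps of size `dt`,
#' payoffs re-evaluated each substep), and at the end of each unit the scoring
#' rule's one-period score-transition map is applied. Masses are clipped at
#' zero and renormalized each substep; a normalization drift beyond 1e-6
#' before renormalization is an error.
#'
#' @param initial a [class_state()].
#' @param params a [pgg_params()].
#' @param rule `"image"`, `"group"` or `"hybrid"` (hybrid mixes the two
#'   transition maps with weight `params$p`).
#' @param horizon number of time units to integrate.
#' @param dt Euler substep (positive, at most 1; `1/dt` substeps per unit).
#' @return Object of class `"pgg_flow"`: list with `states` (a
#'   `(horizon + 1) x 4` matrix of masses, row 0 the initial state), `pC`
#'   (cooperator mass per unit time), `params`, `rule`.
#' @export
integrate_replicator <- function(initial, params,
                                 rule = c("image", "group", "hybrid"),
                                 horizon = 200L, dt = 0.1) {
  rule <- match.arg(rule)
  stopifnot(dt > 0, dt <= 1, horizon >= 0)
  nsub <- max(1L, as.integer(round(1 / dt)))
  h <- as.integer(horizon)
  states <- matrix(NA_real_, nrow = h + 1L, ncol = 4L,
                   dimnames = list(NULL, c("C1", "D1", "C0", "D0")))
  x <- unclass(initial)
  states[1L, ] <- x
  for (t in seq_len(h)) {
    for (sub in seq_len(nsub)) {
      pi <- expected_class_payoffs(class_state(x[["C1"]], x[["D1"]],
                                               x[["C0"]], x[["D0"]]), params)
      x <- x * (1 + dt * (unclass(pi)[1:4] - attr(pi, "pi_bar")))
      x <- pmax(x, 0)
      tot <- sum(x)
      if (abs(tot - 1) > 1e-6 * (1 + dt * 10))
        stop(sprintf("mass normalization failure at t = %d (sum = %.8f)",
                     t, tot), call. = FALSE)
      x <- x / tot
    }
    x <- unclass(score_transition(class_state(x[["C1"]], x[["D1"]],
                                              x[["C0"]], x[["D0"]]),
                                  params, rule))
    states[t + 1L, ] <- x
  }
  structure(list(states = states,
                 pC = states[, "C1"] + states[, "C0"],
                 params = params, rule = rule,
                 horizon = h, dt = dt),
            class = "pgg_flow")
}

#' @export
print.pgg_flow <- function(x, ...) {
  cat(sprintf("pgg_flow: %s scoring, horizon %d (dt = %g)\n",
              x$rule, x$horizon, x$dt))
  cat("  final class masses:\n")
  print(x$states[nrow(x$states), ])
  cat(sprintf("  final cooperator fraction: %.6g\n", x$pC[length(x$pC)]))
  invisible(x)
}

#' @export
plot.pgg_flow <- function(x, ...) {
  t <- seq_len(nrow(x$states)) - 1L
  graphics::matplot(t, x$states, type = "l", lty = 1:4,
                    xlab = "time", ylab = "class mass", ...)
  graphics::legend("right", colnames(x$states), lty = 1:4,
                   col = 1:4, bty = "n")
  invisible(x)
}

#' Perturbation stability probe
#'
#' Injects a small mass `epsilon` of score-1 defectors (taken from the largest
#' cooperator class) into a state and integrates the coupled dynamics. The
#' state is reported stable when cooperation stays high -- final cooperator
#' mass above `(s-1)/s` with the injected D1 mass decayed below `epsilon` --
#' and unstable otherwise. Under image scoring the high-cooperation reference
#' state is stable (free-riding score-1 defectors are exposed and demoted to
#' score 0 in one period, then shrink); under group scoring it is unstable
#' (free-riders inherit their group's high score and keep outgrowing
#' cooperators).
#'
#' @param cs a [class_state()] to probe (e.g. the image-scoring reference
#'   state at [stationary_pD0_image()]).
#' @param params a [pgg_params()].
#' @param rule scoring rule.
#' @param epsilon injected D1 mass (nonnegative; 0 probes the unperturbed
#'   state).
#' @param horizon,dt integration controls, as in [integrate_replicator()].
#' @return List with `verdict` (`"stable"` or `"unstable"`), the perturbed
#'   initial state, the final state, and the full `flow` trajectory.
#' @export
stability_probe <- function(cs, params, rule = c("image", "group", "hybrid"),
                            epsilon = 1e-4, horizon = 200L, dt = 0.1) {
  rule <- match.arg(rule)
  if (epsilon < 0) stop("epsilon must be nonnegative", call. = FALSE)
  if (epsilon == 0)
    return(list(verdict = "stable", initial = cs, final = unclass(cs),
                pC_final = cs[["C1"]] + cs[["C0"]], flow = NULL))
  x <- unclass(cs)
  donor <- if (x[["C1"]] >= x[["C0"]]) "C1" else "C0"
  if (epsilon > x[[donor]])
    stop("epsilon exceeds the available cooperator mass", call. = FALSE)
  x[[donor]] <- x[[donor]] - epsilon
  x[["D1"]] <- x[["D1"]] + epsilon
  start <- class_state(x[["C1"]], x[["D1"]], x[["C0"]], x[["D0"]])
  flow <- integrate_replicator(start, params, rule, horizon, dt)
  fin <- flow$states[nrow(flow$states), ]
  pC_final <- fin[["C1"]] + fin[["C0"]]
  high <- (params$s - 1) / params$s
  stable <- pC_final > high && fin[["D1"]] <= max(epsilon, 1e-12)
  list(verdict = if (stable) "stable" else "unstable",
       initial = start, final = fin, pC_final = pC_final, flow = flow)
}
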