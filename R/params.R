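#' Game parameters for the score-matched public goods game
#'
#' Validates and bundles the constants of the group-interaction public goods
#' game: a population of `n` players is partitioned each period into `k`
#' groups of size `s = n/k` by the ranking of their binary reputation scores,
#' every group plays a linear public goods game with rate of return `r`
#' (marginal per-capita rate `r/s`), and scores are refreshed by image scoring
#' with probability `p` and by group scoring otherwise. `K` is the noise
#' parameter of the Fermi imitation rule.
#'
#' Any two of `n`, `k`, `s` determine the third; all three may be given, in
#' which case they must agree. The standing assumption `r` in `[1, s]` makes a
#' contribution socially beneficial but individually costly.
#'
#' @param n population size (positive integer, `n = k * s`).
#' @param k number of groups (positive integer).
#' @param s group size (positive integer).
#' @param r rate of return, in `[1, s]`.
#' @param p probability that a player's score is refreshed by image scoring
#'   rather than group scoring, in `[0, 1]`. `p = 1` is pure image scoring,
#'   `p = 0` pure group scoring.
#' @param K imitation noise of the Fermi rule (positive; default 0.1).
#'
#' @return An object of class `"pgg_params"`: a list with elements
#'   `n`, `k`, `s`, `r`, `p`, `K`.
#'
#' @examples
#' pgg_params(n = 1500, s = 5, r = 4, p = 1)
#' pgg_params(k = 30, s = 5, r = 1.1, p = 0.01)
#' @export
pgg_params <- function(n = NULL, k = NULL, s = NULL, r, p = 1, K = 0.1) {
  given <- !vapply(list(n, k, s), is.null, logical(1))
  if (sum(given) < 2L)
    stop("supply at least two of n, k, s", call. = FALSE)
  if (is.null(n)) n <- k * s
  if (is.null(k) && n %% s != 0 || is.null(s) && n %% k != 0)
    stop(sprintf("population not divisible into equal groups (n = %s, %s)",
                 format(n),
                 if (is.null(s)) sprintf("k = %s", format(k))
                 else sprintf("s = %s", format(s))), call. = FALSE)
  if (is.null(k)) k <- n / s
  if (is.null(s)) s <- n / k
  for (nm in c("n", "k", "s")) {
    v <- get(nm)
    if (length(v) != 1L || !is.finite(v) || v < 1 || v != round(v))
      stop(sprintf("'%s' must be a positive integer (got %s)", nm,
                   format(v)), call. = FALSE)
  }
  if (n != k * s)
    stop(sprintf("population not divisible into equal groups: n = %d, k = %d, s = %d (need n = k * s)",
                 n, k, s), call. = FALSE)
  if (length(r) != 1L || !is.finite(r) || r < 1 || r > s)
    stop(sprintf("rate of return r = %s outside [1, s] = [1, %d]",
                 format(r), as.integer(s)), call. = FALSE)
  if (length(p) != 1L || !is.finite(p) || p < 0 || p > 1)
    stop("image-scoring probability p must lie in [0, 1]", call. = FALSE)
  if (length(K) != 1L || !is.finite(K) || K <= 0)
    stop("imitation noise K must be positive", call. = FALSE)
  structure(list(n = as.integer(n), k = as.integer(k), s = as.integer(s),
                 r = as.numeric(r), p = as.numeric(p), K = as.numeric(K)),
            class = "pgg_params")
}

#' @export
print.pgg_params <- function(x, ...) {
  cat("Public goods game with score-ranked matching\n")
  cat(sprintf("  n = %d players in k = %d groups of size s = %d\n",
              x$n, x$k, x$s))
  cat(sprintf("  rate of return r = %g (marginal per-capita %g)\n",
              x$r, x$r / x$s))
  cat(sprintf("  image-scoring probability p = %g, Fermi noise K = %g\n",
              x$p, x$K))
  invisible(x)
}

#' Population state of the game
#'
#' A snapshot of the population at one period: each player's hardwired action
#' (contribute the unit or not), binary reputation score, and current group.
#'
#' @param strategies integer vector over \{0, 1\}; 1 = cooperate (contribute),
#'   0 = defect.
#' @param scores integer vector over \{0, 1\}.
#' @param groups integer vector of group indices in `1..k`; each index must
#'   appear exactly `s` times. Group 1 is the best-ranked group.
#' @param params a [pgg_params()] object the state must conform to.
#'
#' @return An object of class `"pgg_state"`.
#' @export
pgg_state <- function(strategies, scores, groups, params) {
  stopifnot(inherits(params, "pgg_params"))
  n <- params$n
  strategies <- as.integer(strategies)
  scores <- as.integer(scores)
  groups <- as.integer(groups)
  if (length(strategies) != n || length(scores) != n || length(groups) != n)
    stop("strategies, scores and groups must all have length n", call. = FALSE)
  if (!all(strategies %in% c(0L, 1L)))
    stop("strategies must be binary (1 = cooperate, 0 = defect)", call. = FALSE)
  if (!all(scores %in% c(0L, 1L)))
    stop("scores must be binary", call. = FALSE)
  tab <- tabulate(groups, nbins = params$k)
  if (any(groups < 1L | groups > params$k) || any(tab != params$s))
    stop("groups must partition the population into k groups of size s",
         call. = FALSE)
  structure(list(strategies = strategies, scores = scores, groups = groups,
                 params = params),
            class = "pgg_state")
}

#' @export
print.pgg_state <- function(x, ...) {
  p <- x$params
  cat(sprintf("pgg_state: n = %d, k = %d groups of s = %d\n", p$n, p$k, p$s))
  cat(sprintf("  cooperators: %d (%.3f), score-1 players: %d (%.3f)\n",
              sum(x$strategies), mean(x$strategies),
              sum(x$scores), mean(x$scores)))
  invisible(x)
}
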