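#' Per-player payoffs of one period of play
#'
#' Every player holds a unit budget. A cooperator contributes it to their
#' group's pot, a defector keeps it. Each group's pot is multiplied by the
#' rate of return `r` and shared equally among its `s` members, so player `i`
#' earns
#' \deqn{\phi_i = (1 - c_i) + \frac{r}{s} \sum_{j \in group(i)} c_j,}
#' with `c_i = 1` for contribution. Within a group a defector always earns
#' exactly one unit more than a cooperator, and total payoffs obey the
#' conservation identity `sum(phi) = n + (r - 1) * sum(c)`.
#'
#' @param state a [pgg_state()].
#' @param params a [pgg_params()]; defaults to the state's own.
#' @return Numeric vector of length `n`, each value in `[0, 1 + r]`.
#' @examples
#' pr <- pgg_params(n = 10, s = 5, r = 4)
#' st <- pgg_state(rep(c(1L, 0L), each = 5), rep(1L, 10),
#'                 rep(1:2, each = 5), pr)
#' compute_payoffs(st)  # full-C group earns r each, full-D group 1 each
#' @export
compute_payoffs <- function(state, params = state$params) {
  g <- state$groups
  contrib_by_group <- as.numeric(
    tabulate(g[state$strategies == 1L], nbins = params$k))
  (1 - state$strategies) + (params$r / params$s) * contrib_by_group[g]
}

#' Image scoring update
#'
#' A player's next-period score reflects their own last contribution: score 1
#' if it exceeded the population-average contribution, 0 if below it, and the
#' previous score is retained on exact equality (the tie can only arise when
#' the whole population played the same action).
#'
#' @param contributions binary vector of last-period contributions.
#' @param prev_scores binary vector of current scores.
#' @return Integer vector of updated binary scores.
#' @export
image_score_update <- function(contributions, prev_scores) {
  stopifnot(length(contributions) == length(prev_scores))
  cbar <- mean(contributions)
  out <- as.integer(prev_scores)
  out[contributions > cbar] <- 1L
  out[contributions < cbar] <- 0L
  out
}

#' Group scoring update
#'
#' Individual actions are invisible: a player's reputation reflects only how
#' their group performed. All members of a group whose total contribution
#' exceeded the overall average contribution receive score 1, members of
#' groups below it receive 0, and exact equality retains the previous score.
#' Because group totals are integers and the average contribution lies in
#' `[0, 1]`, any group that contributed at all is marked as cooperative --
#' free-riders inherit their group's good standing, which is precisely the
#' informational weakness of group-level reputation: only visibly idle groups
#' are marked down, and the tie case (everyone retains their score) occurs
#' exactly in the all-defect population.
#'
#' @inheritParams image_score_update
#' @param groups integer vector of group indices (an equal-size partition).
#' @export
group_score_update <- function(contributions, groups, prev_scores) {
  stopifnot(length(contributions) == length(prev_scores),
            length(groups) == length(prev_scores))
  k <- max(groups)
  totals <- as.numeric(tabulate(groups[contributions == 1], nbins = k))
  cbar <- mean(contributions)
  out <- as.integer(prev_scores)
  gt <- totals[groups]
  out[gt > cbar] <- 1L
  out[gt < cbar] <- 0L
  out
}

#' Hybrid scoring update
#'
#' Each player's score is refreshed, independently of the others, by image
#' scoring with probability `p` and by group scoring with probability `1 - p`.
#' The degenerate mixtures `p = 1` and `p = 0` reproduce the pure rules
#' bit-for-bit under any seed.
#'
#' @inheritParams group_score_update
#' @param p probability of the image-scoring update, in `[0, 1]`.
#' @export
hybrid_score_update <- function(contributions, groups, prev_scores, p) {
  stopifnot(p >= 0, p <= 1)
  if (p == 1) return(image_score_update(contributions, prev_scores))
  if (p == 0) return(group_score_update(contributions, groups, prev_scores))
  img <- image_score_update(contributions, prev_scores)
  grp <- group_score_update(contributions, groups, prev_scores)
  use_image <- stats::runif(length(prev_scores)) < p
  ifelse(use_image, img, grp)
}

#' Score-ranked group matching
#'
#' Players are sorted by score in descending order, with uniformly random
#' tie-breaking, and the sorted sequence is cut into `k` consecutive groups of
#' size `s`. Group 1 therefore holds the top-scored players; no score-0 player
#' is ever placed in a strictly better-ranked group than a score-1 player, and
#' at most one boundary group mixes the two scores.
#'
#' @param scores binary score vector of length `n`.
#' @param params a [pgg_params()].
#' @return Integer vector of group indices in `1..k`.
#' @export
match_by_score <- function(scores, params) {
  n <- params$n
  stopifnot(length(scores) == n)
  ord <- order(-as.integer(scores), stats::runif(n))
  out <- integer(n)
  out[ord] <- rep(seq_len(params$k), each = params$s)
  out
}
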