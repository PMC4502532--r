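# shared helpers for the suite

# closed form for the interior image-scoring rest point, derived by hand from
# the reference-state payoffs pi_C1 = r, pi_C0 = (s - n x) r/s,
# pi_D0 = 1 + (s - n x) r/s: setting pi_D0 = pibar and cancelling the
# quadratic terms leaves 1 - x (1 + r (n - s)/s) = 0.
pD0_closed_form <- function(n, s, r) s / (s + r * (n - s))

# a random valid population state for property loops
random_state <- function(params, coop_prob = 0.5) {
  n <- params$n
  strat <- as.integer(stats::runif(n) < coop_prob)
  scores <- as.integer(stats::runif(n) < 0.5)
  groups <- sample(rep(seq_len(params$k), each = params$s))
  pgg_state(strat, scores, groups, params)
}

# per-class empirical mean payoffs under repeated score-ranked matching
sampled_class_payoffs <- function(strat, scores, params, draws) {
  sel <- list(C1 = strat == 1L & scores == 1L,
              D1 = strat == 0L & scores == 1L,
              C0 = strat == 1L & scores == 0L,
              D0 = strat == 0L & scores == 0L)
  sums <- sq <- numeric(4L)
  for (d in seq_len(draws)) {
    g <- match_by_score(scores, params)
    phi <- compute_payoffs(list(strategies = strat, scores = scores,
                                groups = g), params)
    m <- vapply(sel, function(s_) mean(phi[s_]), numeric(1))
    sums <- sums + m
    sq <- sq + m^2
  }
  mean_ <- sums / draws
  list(mean = mean_, se = sqrt(pmax(sq / draws - mean_^2, 0) / draws))
}
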