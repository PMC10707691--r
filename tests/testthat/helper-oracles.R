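# Independent oracles used across the suite. These re-derive expected
# results by brute force or closed form, never by calling the code paths
# they check.

# O(n^2) optimal-partitioning dynamic program for the penalized-SSE
# segmentation objective; returns 1-based segment end indices.
dp_segment_oracle <- function(y, beta) {
  n <- length(y)
  cs <- cumsum(c(0, y))
  cs2 <- cumsum(c(0, y^2))
  sse <- function(s, t) (cs2[t + 1] - cs2[s + 1]) -
    (cs[t + 1] - cs[s + 1])^2 / (t - s)
  F <- c(-beta, rep(Inf, n))
  last <- integer(n + 1)
  for (t in 1:n) {
    for (s in 0:(t - 1)) {
      v <- F[s + 1] + sse(s, t) + beta
      if (v < F[t + 1]) {
        F[t + 1] <- v
        last[t + 1] <- s
      }
    }
  }
  ends <- integer(0)
  t <- n
  while (t > 0) {
    ends <- c(t, ends)
    t <- last[t + 1]
  }
  ends
}

# the same penalty rule segment_arm documents; recomputed here so the oracle
# and the implementation run on identical beta
oracle_penalty <- function(y, penalty_scale = 3.0) {
  sigma <- mad(diff(y)) / sqrt(2)
  beta <- penalty_scale * sigma^2 * log(length(y))
  if (!is.finite(beta) || beta <= 0) beta <- 1e-12
  beta
}

# two-sided Fisher p-value by full hypergeometric enumeration over all
# tables with the observed margins (probability <= observed rule)
fisher_enum_p <- function(t) {
  r1 <- sum(t[1, ])
  c1 <- sum(t[, 1])
  N <- sum(t)
  a <- max(0, r1 + c1 - N):min(r1, c1)
  probs <- dhyper(a, c1, N - c1, r1)
  pobs <- dhyper(t[1, 1], c1, N - c1, r1)
  sum(probs[probs <= pobs * (1 + 1e-7)])
}

# k-group log-rank statistic from first principles (observed minus expected
# under the hypergeometric at each distinct event time)
logrank_oracle_chisq <- function(time, event, group) {
  group <- as.factor(group)
  k <- nlevels(group)
  O <- E <- rep(0, k)
  V <- matrix(0, k, k)
  for (tt in sort(unique(time[event == 1]))) {
    at_risk <- time >= tt
    n <- sum(at_risk)
    d <- sum(event == 1 & time == tt)
    ni <- vapply(levels(group), function(g) sum(at_risk & group == g),
                 numeric(1))
    di <- vapply(levels(group), function(g)
      sum(event == 1 & time == tt & group == g), numeric(1))
    O <- O + di
    E <- E + ni * d / n
    if (n > 1) {
      for (i in 1:k) for (j in 1:k) {
        V[i, j] <- V[i, j] +
          d * (n - d) / (n - 1) *
          (ni[i] * (i == j) / n - ni[i] * ni[j] / n^2)
      }
    }
  }
  z <- (O - E)[-1]
  drop(t(z) %*% solve(V[-1, -1, drop = FALSE]) %*% z)
}

# Breslow partial log-likelihood for a single binary covariate, for 1-D
# maximization as an independent Cox oracle
breslow_loglik <- function(beta, time, event, x) {
  ll <- 0
  for (tt in sort(unique(time[event == 1]))) {
    dead <- event == 1 & time == tt
    at_risk <- time >= tt
    ll <- ll + beta * sum(x[dead]) -
      sum(dead) * log(sum(exp(beta * x[at_risk])))
  }
  ll
}

# simulate one pipeline sample end-to-end; returns truth and estimate
simulate_and_score <- function(seed, genome = reduced_genome(),
                               base_window = 5000,
                               windows = c(5, 25, 50, 100, 500, 1000) * 1000) {
  cfg <- sim_config(seed = seed)
  target <- with(list(), {
    set.seed(seed)
    sample(cfg$lga_target_range[1]:cfg$lga_target_range[2], 1)
  })
  tp <- simulate_truth_profile(genome, target, seed = seed, config = cfg)
  bins <- simulate_bin_counts(tp, genome, base_window, cfg)
  res <- gia_score(bins, genome, windows = windows)
  list(truth = tp, result = res)
}
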