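# independent oracles used by the tests

# exhaustive least-squares changepoint search with 0, 1 or 2 changepoints
# under the same penalized cost as the caller: the brute-force reference for
# small instances
exhaustive_cp_oracle <- function(x, beta) {
  n <- length(x)
  cs <- c(0, cumsum(x))
  cs2 <- c(0, cumsum(x^2))
  sse <- function(a, b) {
    # segment (a, b], 0-based boundaries
    (cs2[b + 1] - cs2[a + 1]) - (cs[b + 1] - cs[a + 1])^2 / (b - a)
  }
  best <- list(cost = sse(0, n), cps = integer(0))
  for (k1 in 1:(n - 1)) {
    c1 <- sse(0, k1) + sse(k1, n) + beta
    if (c1 < best$cost) best <- list(cost = c1, cps = k1)
  }
  if (n >= 3) {
    for (k1 in 1:(n - 2)) {
      left <- sse(0, k1)
      for (k2 in (k1 + 1):(n - 1)) {
        c2 <- left + sse(k1, k2) + sse(k2, n) + 2 * beta
        if (c2 < best$cost) best <- list(cost = c2, cps = c(k1, k2))
      }
    }
  }
  best
}

penalized_cost <- function(x, cps, beta) {
  bounds <- c(0, cps, length(x))
  cost <- length(cps) * beta
  for (i in seq_len(length(bounds) - 1)) {
    seg <- x[(bounds[i] + 1):bounds[i + 1]]
    cost <- cost + sum((seg - mean(seg))^2)
  }
  cost
}

# one-sided Fisher exact p by direct hypergeometric tail enumeration
fisher_tail_oracle <- function(both, a_only, b_only, neither,
                               direction = c("greater", "less")) {
  direction <- match.arg(direction)
  m <- both + a_only          # samples mutated in gene a
  k <- both + b_only          # samples mutated in gene b
  n <- both + a_only + b_only + neither
  support <- max(0, m + k - n):min(m, k)
  probs <- stats::dhyper(support, m, n - m, k)
  if (direction == "greater") {
    sum(probs[support >= both])
  } else {
    sum(probs[support <= both])
  }
}
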