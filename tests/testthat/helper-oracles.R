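# Independent brute-force oracles used across tests. These deliberately
# avoid the package's own rank/statistic code paths.

# Mid-ranks by pairwise counting: rank_i = #{x_j < x_i} + (#{x_j == x_i} + 1)/2
oracle_midranks <- function(x) {
  vapply(seq_along(x), function(i) {
    sum(x < x[i]) + (sum(x == x[i]) + 1) / 2
  }, numeric(1))
}

oracle_rank_stats <- function(pre, post) {
  ns <- length(pre); nt <- length(post); n <- ns + nt
  r <- oracle_midranks(c(pre, post))
  rs <- sum(r[seq_len(ns)])
  rt <- sum(r[-seq_len(ns)])
  list(U_S = ns * nt + ns * (ns + 1) / 2 - rs,
       U_T = ns * nt + nt * (nt + 1) / 2 - rt,
       M_prime = sum((r[seq_len(ns)] - (n + 1) / 2) ^ 2))
}

# OLS sum of squared errors via the normal equations (no lm()).
oracle_sse <- function(x, y) {
  X <- cbind(1, x)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  sum((y - X %*% beta) ^ 2)
}

# A synthetic monthly data frame with explicit P and Q values.
make_monthly <- function(p, q, start = "1990-01-01") {
  n <- length(p)
  data.frame(date = seq(as.Date(start), by = "month", length.out = n),
             P_mm = p, Q_mm = q)
}
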