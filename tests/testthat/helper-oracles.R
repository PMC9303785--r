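# Independent oracles: deliberately naive implementations kept separate from
# the package's code paths.

# Logistic regression by hand-written iteratively reweighted least squares.
irls_logistic <- function(X, y, tol = 1e-12, maxit = 100) {
  beta <- rep(0, ncol(X))
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    mu <- 1 / (1 + exp(-eta))
    w <- mu * (1 - mu)
    z <- eta + (y - mu) / w
    fit <- lm.wfit(X, z, w)
    new <- fit$coefficients
    if (max(abs(new - beta)) < tol) {
      beta <- new
      break
    }
    beta <- new
  }
  eta <- drop(X %*% beta)
  mu <- 1 / (1 + exp(-eta))
  W <- diag(as.numeric(mu * (1 - mu)))
  cov <- solve(t(X) %*% W %*% X)
  list(coef = beta, se = sqrt(diag(cov)))
}

# Hypergeometric upper-tail p by exhaustive enumeration of all C(N, n) draws.
hyper_enum <- function(N, K, n, k) {
  draws <- combn(N, n)
  hits <- colSums(draws <= K)  # treat items 1..K as the set
  mean(hits >= k)
}

# Brute-force miRNA inclusion: build the retained base set explicitly and ask
# whether every precursor base is in it. The junction base is disrupted.
inclusion_oracle <- function(prec_start, prec_end, junction, gene_start,
                             gene_end, strand, role) {
  downstream_kept <- (role == "3prime" && strand == "+") ||
    (role == "5prime" && strand == "-")
  retained <- if (downstream_kept) {
    if (junction + 1 > gene_end) integer(0) else seq(junction + 1, gene_end)
  } else {
    if (junction - 1 < gene_start) integer(0) else seq(gene_start, junction - 1)
  }
  retained <- retained[retained >= gene_start & retained <= gene_end]
  if (all(seq(prec_start, prec_end) %in% retained)) "INCLUDED" else "MIREXCL"
}

# Two-sided exact binomial p with the "outcomes no more likely than observed"
# rule (the dispersion-zero limit of the NB exact test).
binom_two_sided <- function(a, t, pr) {
  f <- dbinom(0:t, t, pr)
  sum(f[f <= f[a + 1] * (1 + 1e-8)])
}
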