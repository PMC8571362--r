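# Independent oracles and small fixture builders shared across tests.

# closed-form OLS: (X'X)^{-1} X'y, with plain textbook standard errors
ols_oracle <- function(y, x) {
  X <- cbind(1, as.matrix(x))
  XtXinv <- solve(crossprod(X))
  beta <- drop(XtXinv %*% crossprod(X, y))
  r <- y - drop(X %*% beta)
  s2 <- sum(r^2) / (length(y) - ncol(X))
  list(beta = beta, se = sqrt(diag(XtXinv) * s2), rss = sum(r^2))
}

# brute-force Benjamini-Hochberg step-up from the definition:
# q_(i) = min_{j >= i} min(1, m * p_(j) / j)
bh_bruteforce <- function(p) {
  m <- length(p)
  ord <- order(p)
  ranked <- p[ord]
  q <- pmin(1, m * ranked / seq_len(m))
  for (i in (m - 1):1) if (m > 1) q[i] <- min(q[i], q[i + 1])
  out <- numeric(m)
  out[ord] <- q
  out
}

# replicate z draws for one screen group: mean effect + iid noise
zgroup <- function(n, mean, sd = 0.5) stats::rnorm(n, mean, sd)

# small cohort scan fixture: two common dosage predictors, one trait
make_two_snp_data <- function(n = 5000, maf = 0.2, beta_a = 0, beta_b = 0,
                              beta_ab = 0, sd = 1) {
  x1 <- stats::rbinom(n, 2, maf)
  x2 <- stats::rbinom(n, 2, maf)
  y <- beta_a * x1 + beta_b * x2 + beta_ab * x1 * x2 + stats::rnorm(n, 0, sd)
  names(y) <- names(x1) <- names(x2) <- sprintf("S%04d", seq_len(n))
  list(y = y, x1 = x1, x2 = x2)
}
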