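# Independent oracles used across the suite. These deliberately avoid the
# code paths they check: brute-force enumeration for Fisher's test,
# numerical integration for the t CDF, direct formula algebra elsewhere.

# two-sided two-sample pooled t-test by direct formula + numerically
# integrated t density (no pt/pbeta)
oracle_t_test <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  sp2 <- (sum((x - mean(x))^2) + sum((y - mean(y))^2)) / (n1 + n2 - 2)
  t <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  df <- n1 + n2 - 2
  dens <- function(u) {
    exp(lgamma((df + 1) / 2) - lgamma(df / 2)) / sqrt(df * pi) *
      (1 + u^2 / df)^(-(df + 1) / 2)
  }
  tail <- integrate(dens, abs(t), Inf, rel.tol = 1e-12)$value
  list(t = t, p = 2 * tail)
}

# two-sided Fisher exact p by exhaustive enumeration of all tables with
# the observed margins, summing probabilities <= that of the observed
# table (R's fisher.test convention, up to a 1e-7 relative nudge)
oracle_fisher <- function(tab) {
  a <- tab[1, 1]; b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]
  r1 <- a + b; r2 <- c + d; c1 <- a + c; n <- a + b + c + d
  prob <- function(x) {
    exp(lchoose(r1, x) + lchoose(r2, c1 - x) - lchoose(n, c1))
  }
  xs <- max(0, c1 - r2):min(r1, c1)
  ps <- vapply(xs, prob, numeric(1))
  obs <- prob(a)
  sum(ps[ps <= obs * (1 + 1e-7)])
}

# adjusted Rand index between two partitions
oracle_ari <- function(a, b) {
  tab <- table(a, b)
  sij <- sum(choose(tab, 2))
  si <- sum(choose(rowSums(tab), 2))
  sj <- sum(choose(colSums(tab), 2))
  n2 <- choose(sum(tab), 2)
  expected <- si * sj / n2
  (sij - expected) / ((si + sj) / 2 - expected)
}

# windowed mean of -log10 p within one chromosome, naive double loop
oracle_smooth <- function(p, radius) {
  s <- -log10(p)
  n <- length(s)
  out <- numeric(n)
  for (i in seq_len(n)) {
    w <- max(1, i - radius):min(n, i + radius)
    out[i] <- mean(s[w])
  }
  10^(-out)
}

# small expression scenario for fast structural tests (same archetype
# patterns, fewer genes)
small_expr_scenario <- function(n_genes = 400, noise_sd = 0.3) {
  expression_scenario(n_genes = n_genes, noise_sd = noise_sd)
}
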