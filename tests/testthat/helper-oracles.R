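# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths (and the wrapped stats:: tests) so agreement is
# a genuine cross-check.

# Centroid of x -> min(alpha, membership(x)) over [lo, hi] by adaptive
# quadrature, independent of the package's fixed-grid defuzzifier.
oracle_clipped_centroid <- function(mf, alpha, lo, hi) {
  f <- function(x) pmin(alpha, membership(x, mf))
  num <- stats::integrate(function(x) x * f(x), lo, hi,
                          subdivisions = 2000L, rel.tol = 1e-10)$value
  den <- stats::integrate(f, lo, hi,
                          subdivisions = 2000L, rel.tol = 1e-10)$value
  num / den
}

# Mid-ranks computed from first principles (no rank()).
oracle_midranks <- function(x) {
  n <- length(x)
  r <- numeric(n)
  for (i in seq_len(n)) {
    r[i] <- sum(x < x[i]) + (sum(x == x[i]) + 1) / 2
  }
  r
}

# Kruskal-Wallis H with tie correction, assembled from the definition.
oracle_kw_h <- function(values, groups) {
  groups <- as.factor(groups)
  N <- length(values)
  r <- oracle_midranks(values)
  h <- 0
  for (g in levels(groups)) {
    idx <- groups == g
    h <- h + sum(r[idx])^2 / sum(idx)
  }
  h <- 12 / (N * (N + 1)) * h - 3 * (N + 1)
  ties <- table(values)
  correction <- 1 - sum(ties^3 - ties) / (N^3 - N)
  h / correction
}

# Signed-rank statistic (sum of positive-difference ranks) and exact
# two-sided p by full enumeration of the 2^n sign assignments.
oracle_signed_rank <- function(d) {
  stopifnot(all(d != 0))
  r <- oracle_midranks(abs(d))
  v <- sum(r[d > 0])
  n <- length(d)
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  vs <- as.vector(signs %*% r)
  p <- min(1, 2 * min(mean(vs <= v), mean(vs >= v)))
  list(statistic = v, p_value = p)
}

# Spearman rho from first principles: Pearson correlation of mid-ranks.
oracle_spearman <- function(x, y) {
  rx <- oracle_midranks(x); ry <- oracle_midranks(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# Small deterministic cohort for structural tests.
toy_cohort <- function(n = 60, seed = 42) {
  cfg <- generator_config(n = n, seed = seed)
  generate_copula(cfg)
}
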