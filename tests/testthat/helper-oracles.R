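# Independent oracles, deliberately implemented from first principles and
# kept separate from the package code paths they check.

# Median-effect fit object from known true parameters (no fitting involved).
meFit <- function(m, Dm, drug = "x") {
  new("MedianEffectFit", drug = drug, m = m, Dm = Dm, r = 1, nPoints = 5L,
      nClipped = 0L, status = "ok")
}

# Closed-form survival function of a chi-square with an even number of
# degrees of freedom 2k (Erlang): S(X) = exp(-X/2) * sum_{j<k} (X/2)^j / j!
oracle_chisq_upper_even <- function(X, k) {
  j <- 0:(k - 1)
  exp(-X / 2) * sum((X / 2)^j / factorial(j))
}

# Newton-Raphson maximiser of the Cox partial likelihood, Breslow form
# (identical to Efron when there are no tied event times).
oracle_cox_z <- function(time, event, x, tol = 1e-12, maxit = 100) {
  ord <- order(time)
  time <- time[ord]; event <- event[ord]; x <- x[ord]
  n <- length(time)
  beta <- 0
  for (it in seq_len(maxit)) {
    U <- 0; I <- 0
    for (i in which(event == 1)) {
      risk <- which(time >= time[i])
      w <- exp(beta * x[risk])
      s0 <- sum(w); s1 <- sum(w * x[risk]); s2 <- sum(w * x[risk]^2)
      U <- U + x[i] - s1 / s0
      I <- I + (s2 / s0 - (s1 / s0)^2)
    }
    step <- U / I
    beta <- beta + step
    if (abs(step) < tol) break
  }
  list(beta = beta, se = 1 / sqrt(I), z = beta * sqrt(I))
}

# Upper-tail hypergeometric probability by explicit summation over the
# enrichment table: P(X >= k) with K set genes among N, n draws.
oracle_hypergeom_upper <- function(k, n, K, N) {
  j <- k:min(n, K)
  sum(choose(K, j) * choose(N - K, n - j) / choose(N, n))
}

# One-liner literal impact score: F'IC50 * sum_t Fexp, straight from the
# displayed formulas.
oracle_impact_literal <- function(exprTreatMat, exprControl, ic50k, ic50c) {
  fexpSum <- rowSums(log2(exprTreatMat) - log2(exprControl))
  f <- ic50k / ic50c
  fp <- (f - min(f)) / (max(f) - min(f))
  fp * fexpSum
}

# Exact median-effect fraction affected.
oracle_fa <- function(D, m, Dm) (D / Dm)^m / (1 + (D / Dm)^m)
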