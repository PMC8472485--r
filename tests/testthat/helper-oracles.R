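# Brute-force reference: pooled within-class covariance and Ledoit-Wolf
# intensity computed by explicit loops over samples, then both Gaussian
# discriminant functions evaluated per test point. Independent of the
# package's vectorized implementation.
oracleSlda <- function(X, y, Xtest) {
  mu0 <- colMeans(X[y == 0, , drop = FALSE])
  mu1 <- colMeans(X[y == 1, , drop = FALSE])
  n <- nrow(X); d <- ncol(X)
  Xc <- X
  for (i in seq_len(n))
    Xc[i, ] <- X[i, ] - if (y[i] == 1) mu1 else mu0
  S <- matrix(0, d, d)
  for (i in seq_len(n)) S <- S + outer(Xc[i, ], Xc[i, ])
  S <- S / n
  m <- mean(diag(S))
  d2 <- sum((S - diag(m, d))^2) / d
  if (d2 < .Machine$double.eps) {
    gamma <- 0
  } else {
    b2bar <- 0
    for (i in seq_len(n))
      b2bar <- b2bar + sum((outer(Xc[i, ], Xc[i, ]) - S)^2)
    b2bar <- b2bar / (n^2 * d)
    gamma <- min(b2bar, d2) / d2
  }
  Sig <- (1 - gamma) * S + diag(gamma * m, d)
  SigInv <- solve(Sig)
  disc <- function(x, mu) sum(x * (SigInv %*% mu)) -
    sum(mu * (SigInv %*% mu)) / 2 + log(0.5)
  labs <- apply(Xtest, 1, function(x) {
    d1 <- disc(x, mu1); d0 <- disc(x, mu0)
    if (d1 > d0) "ErrP" else "NonErrP"
  })
  list(gamma = gamma, labels = labs)
}

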