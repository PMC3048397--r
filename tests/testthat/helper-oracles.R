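# Independent numerical oracles used to cross-check the package's own
# implementations. These deliberately take different computational routes
# from the code under test.

# Entropy maximization on the n-simplex with a fixed mean, solved as a
# generic penalized optimization over a softmax parameterization (no
# Lagrange-multiplier root-finding): maximize H(p) = -sum p log p subject to
# sum(p) = 1 (automatic via softmax) and sum(i * p) = mu (quadratic
# penalty). Suitable for small n.
entropy_oracle <- function(n, mu) {
  i <- seq_len(n)
  if (n == 2) {  # constraints fully determine p
    p2 <- mu - 1
    return(c(1 - p2, p2))
  }
  # The two equality constraints are eliminated exactly: free variables are
  # p_1..p_{n-2}; p_{n-1} and p_n are solved from sum(p) = 1 and
  # sum(i p) = mu. A vanishing log-barrier keeps iterates interior.
  full_p <- function(q) {
    A <- 1 - sum(q)
    B <- mu - sum(i[seq_along(q)] * q)
    c(q, n * A - B, B - (n - 1) * A)
  }
  # strictly feasible start: mix uniform with a boundary point mass
  M <- (n + 1) / 2
  p0 <- rep(1 / n, n)
  if (mu < M) {
    t0 <- (M - mu) / (M - 1)
    p0[1] <- p0[1] + 0  # mixture below
    p0 <- (1 - t0) * rep(1 / n, n) + t0 * c(1, rep(0, n - 1))
  } else if (mu > M) {
    t0 <- (mu - M) / (n - M)
    p0 <- (1 - t0) * rep(1 / n, n) + t0 * c(rep(0, n - 1), 1)
  }
  q <- p0[seq_len(n - 2)]
  j <- seq_len(n - 2)
  # dp_{n-1}/dq_j = j - n ; dp_n/dq_j = (n - 1) - j
  for (bar in 10^c(-2, -4, -6, -9, -12)) {
    obj <- function(q) {
      p <- full_p(q)
      if (any(p <= 0)) return(1e6 * (1 + sum(pmax(-p, 0))))
      sum(p * log(p)) - bar * sum(log(p))
    }
    grad <- function(q) {
      p <- full_p(q)
      if (any(p <= 0)) {
        viol <- as.numeric(p <= 0)
        return(-1e6 * (viol[j] + viol[n - 1] * (j - n) +
                         viol[n] * ((n - 1) - j)))
      }
      gp <- (1 + log(p)) - bar / p
      gp[j] + gp[n - 1] * (j - n) + gp[n] * ((n - 1) - j)
    }
    q <- stats::optim(q, obj, grad, method = "BFGS",
                      control = list(maxit = 20000, reltol = 1e-16))$par
  }
  full_p(q)
}

# Two-tailed Fisher's exact test by full enumeration of all 2x2 tables with
# the observed margins: sum the hypergeometric probabilities of every table
# whose probability does not exceed the observed table's.
fisher_enum_oracle <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c
  xs <- max(0, c1 - r2):min(r1, c1)
  probs <- stats::dhyper(xs, r1, r2, c1)
  p_obs <- stats::dhyper(a, r1, r2, c1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Population SD, duplicated here so the tests do not lean on the package's
# internal helper.
oracle_pop_sd <- function(x) sqrt(mean((x - mean(x))^2))
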