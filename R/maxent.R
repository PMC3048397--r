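#' Solve the discrete maximum-entropy distribution with a fixed mean
#'
#' Finds the probability distribution on the support \eqn{\{1, 2, \dots, n\}}
#' that maximizes Shannon entropy subject to normalization and a fixed mean
#' \eqn{\mu}. By the method of Lagrange multipliers the solution has the
#' exponential form \eqn{p_i = C e^{-\lambda i}}, where the constants
#' \eqn{C} and \eqn{\lambda} are determined by the two constraints
#' \eqn{\sum_i p_i = 1} and \eqn{\sum_i i\, p_i = \mu}.
#'
#' In a bipartite network the animal-side null uses \code{n = S_P} (a
#' consumer can touch at most every plant) and \code{mu = L / S_A}; the
#' plant-side null uses \code{n = S_A} and \code{mu = L / S_P}. Degrees start
#' at 1: taxa with no links are not part of a degree distribution.
#'
#' \eqn{\lambda} is the unique root of \eqn{\mathrm{mean}(\lambda) = \mu},
#' where \eqn{\mathrm{mean}(\lambda) = \sum_i i e^{-\lambda i} / \sum_i
#' e^{-\lambda i}}; the mean is strictly decreasing in \eqn{\lambda}, so a
#' geometrically grown bracket plus Brent root-finding (with a Newton polish
#' to \code{|mean - mu| <= 1e-10}) is globally safe. The pmf is assembled in
#' log space with a log-sum-exp normalizer so large \eqn{|\lambda|} or large
#' \code{n} do not overflow. Sign convention: \eqn{\lambda > 0} iff
#' \eqn{\mu < (n+1)/2} (decreasing, skewed-to-specialists shape).
#'
#' The boundary cases \code{mu = 1} and \code{mu = n} are degenerate point
#' masses (\eqn{\lambda \to \pm\infty}); they are returned as explicit
#' point-mass distributions flagged \code{degenerate = TRUE} rather than as
#' errors, because very small empirical webs can hit these bounds. Sampling
#' and \code{\link{maxent_sd}} (= 0) remain well defined for them.
#'
#' @param n integer support maximum; the support is \code{1:n}.
#' @param mu target mean link count, with \code{1 <= mu <= n}.
#' @return An object of class \code{"maxent_dist"}: a list with elements
#'   \code{n}, \code{mu}, \code{lam} (the multiplier \eqn{\lambda}, possibly
#'   \code{Inf}/\code{-Inf} when degenerate), \code{log_C} (log normalizing
#'   constant), \code{pmf} (numeric vector of length \code{n}) and
#'   \code{degenerate} (logical).
#' @examples
#' d <- solve_maxent(10, 2.5)
#' sum(d$pmf)                    # 1
#' sum(seq_len(10) * d$pmf)      # 2.5
#' solve_maxent(5, 3)$pmf        # uniform: mu = (n + 1)/2 forces lambda = 0
#' @seealso [maxent_sd()], [sample_degree_sequence()], [g_statistic()]
#' @export
solve_maxent <- function(n, mu) {
  if (length(n) != 1L || !is.finite(n) || n < 1 || n != round(n))
    stop("'n' must be a single positive integer")
  n <- as.integer(n)
  if (length(mu) != 1L || !is.finite(mu))
    stop("'mu' must be a single finite number")
  if (mu < 1 || mu > n)
    stop(sprintf("'mu' must lie in [1, n] = [1, %d]; got %g", n, mu))

  i <- seq_len(n)

  if (n == 1L || mu == 1 || mu == n) {
    # Point mass at the boundary the mean constraint pins down.
    at <- if (mu == n) n else 1L
    pmf <- numeric(n)
    pmf[at] <- 1
    return(new_maxent_dist(n, mu, lam = if (at == 1L) Inf else -Inf,
                           log_C = NA_real_, pmf = pmf, degenerate = TRUE))
  }

  mean_at <- function(lam) {
    w <- -lam * i
    w <- exp(w - max(w))
    sum(i * w) / sum(w)
  }

  # mean_at() is strictly decreasing with range (1, n); grow the bracket
  # geometrically until it straddles mu.
  hi <- 1
  while (mean_at(-hi) < mu || mean_at(hi) > mu) {
    hi <- hi * 2
    if (hi > 2^40) stop("failed to bracket lambda")  # unreachable for interior mu
  }
  lam <- stats::uniroot(function(l) mean_at(l) - mu, lower = -hi, upper = hi,
                        tol = .Machine$double.eps^0.5)$root

  # Newton polish: d mean / d lambda = -Var, so lam <- lam + (mean - mu)/Var.
  for (iter in 1:100) {
    w <- -lam * i
    w <- exp(w - max(w))
    p <- w / sum(w)
    m <- sum(i * p)
    if (abs(m - mu) <= 1e-10) break
    v <- sum(i * i * p) - m * m
    lam <- lam + (m - mu) / v
  }

  logw <- -lam * i
  log_C <- -logsumexp(logw)
  pmf <- exp(logw + log_C)
  new_maxent_dist(n, mu, lam, log_C, pmf, degenerate = FALSE)
}

new_maxent_dist <- function(n, mu, lam, log_C, pmf, degenerate) {
  structure(list(n = n, mu = mu, lam = lam, log_C = log_C, pmf = pmf,
                 degenerate = degenerate),
            class = "maxent_dist")
}

#' @export
print.maxent_dist <- function(x, ...) {
  cat(sprintf("MaxEnt distribution on {1..%d}, mean %.6g\n", x$n, x$mu))
  if (x$degenerate) {
    cat("  degenerate point mass (mean at support boundary)\n")
  } else {
    cat(sprintf("  lambda = %.6g, sd = %.6g\n", x$lam, maxent_sd(x)))
  }
  invisible(x)
}

#' Standard deviation of a MaxEnt distribution
#'
#' The model width \eqn{\sigma_M = \sqrt{\sum_i i^2 p_i - \mu^2}} used as the
#' denominator of the relative width \eqn{W = \log(\sigma_O / \sigma_M)}.
#' Zero for a degenerate point mass.
#'
#' @param dist a \code{"maxent_dist"} from [solve_maxent()].
#' @return Nonnegative scalar \eqn{\sigma_M}.
#' @export
maxent_sd <- function(dist) {
  stopifnot(inherits(dist, "maxent_dist"))
  if (dist$degenerate) return(0)
  i <- seq_len(dist$n)
  sqrt(max(sum(i * i * dist$pmf) - dist$mu^2, 0))
}

#' Sample a degree sequence from a MaxEnt distribution
#'
#' Draws \code{count} independent degrees from the model's pmf, i.e. one
#' simulated degree sequence for a side of a bipartite network with
#' \code{count} taxa. Reproducible via \code{seed} (or the caller's RNG state
#' when \code{seed} is \code{NULL}).
#'
#' @param dist a \code{"maxent_dist"}.
#' @param count number of taxa (sequence length), \code{count >= 1}.
#' @param side label for the sampled sequence, \code{"plant"} or
#'   \code{"animal"}.
#' @param seed optional integer seed.
#' @return A [degree_sequence()] of length \code{count} with values in
#'   \code{1:dist$n}.
#' @export
sample_degree_sequence <- function(dist, count, side = "animal", seed = NULL) {
  stopifnot(inherits(dist, "maxent_dist"))
  if (length(count) != 1L || !is.finite(count) || count < 1)
    stop("'count' must be a positive integer")
  set_seed_if_given(seed)
  degree_sequence(sample.int(dist$n, size = as.integer(count), replace = TRUE,
                             prob = dist$pmf),
                  side = side)
}

#' Write a MaxEnt distribution as a two-column table
#'
#' Serializes the pmf to plain text with columns \code{degree} and
#' \code{probability}.
#'
#' @param dist a \code{"maxent_dist"}.
#' @param path output file path.
#' @param sep field separator.
#' @export
write_maxent <- function(dist, path, sep = "\t") {
  stopifnot(inherits(dist, "maxent_dist"))
  utils::write.table(data.frame(degree = seq_len(dist$n), probability = dist$pmf),
                     path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}
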