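#' Likelihood-ratio (G) statistic against a MaxEnt null
#'
#' Compares an observed degree sequence to the expected frequencies under a
#' MaxEnt model: \eqn{G = 2 \sum_i O_i \ln(O_i / E_i)} where \eqn{O_i} is the
#' observed count of degree \eqn{i}, \eqn{E_i = N p_i} the expected count
#' (\eqn{N} taxa), and \eqn{i} runs over the support with nonzero expected
#' value. Terms with \eqn{O_i = 0} contribute zero. An observed degree where
#' the model puts no mass (only possible for a degenerate model) yields
#' \code{Inf}.
#'
#' @param observed a [degree_sequence()] or positive integer vector.
#' @param dist a [solve_maxent()] distribution with \code{dist$n >=
#'   max(observed)}.
#' @return The scalar G statistic.
#' @examples
#' d <- solve_maxent(4, 2.5)           # uniform on 1..4
#' g_statistic(c(1, 2, 3, 4), d)       # 0: observed == expected
#' @export
g_statistic <- function(observed, dist) {
  stopifnot(inherits(dist, "maxent_dist"))
  v <- as_degree_values(observed)
  if (max(v) > dist$n)
    stop(sprintf("observed degree %d exceeds model support maximum %d",
                 max(v), dist$n))
  O <- tabulate(v, nbins = dist$n)
  E <- length(v) * dist$pmf
  if (any(O > 0 & E == 0)) return(Inf)
  k <- O > 0
  2 * sum(O[k] * log(O[k] / E[k]))
}

# One batch of null trials: `trials` sequences of length N drawn from dist,
# with per-trial G and per-trial relative width W returned. Shared by
# goodness_of_fit(), w95() and maxent_fit(). Vectorized: all draws in one
# sample.int() call, per-trial degree histograms via an offset tabulate().
null_trial_stats <- function(dist, N, trials, want_G = TRUE, want_W = TRUE) {
  n <- dist$n
  draws <- sample.int(n, size = N * trials, replace = TRUE, prob = dist$pmf)
  out <- list()
  if (want_G) {
    offset <- rep(0:(trials - 1L), each = N) * n
    counts <- tabulate(draws + offset, nbins = n * trials)
    dim(counts) <- c(n, trials)
    E <- N * dist$pmf
    term <- counts * (log(counts) - log(E))  # 0*log(0) -> NaN, zeroed below
    term[counts == 0L] <- 0
    out$G <- 2 * .colSums(term, n, trials)
  }
  if (want_W) {
    dim(draws) <- c(N, trials)
    m1 <- .colMeans(draws, N, trials)
    m2 <- .colMeans(draws * draws, N, trials)
    sd_t <- sqrt(pmax(m2 - m1 * m1, 0))
    sigma_M <- maxent_sd(dist)
    out$W <- ifelse(sd_t > 0, log(sd_t / sigma_M), -Inf)
  }
  out
}

#' Randomized goodness of fit f_G
#'
#' Monte-Carlo tail probability of the G statistic: in each trial a degree
#' sequence of the same length as the observed one is drawn from the MaxEnt
#' model and its G computed; \code{f_G} is the fraction of trials in which
#' the observed G strictly exceeds the trial G. Values \code{f_G >= 0.95}
#' reject the null at the 95% level; under the null \code{f_G} is
#' approximately uniform, so rejection occurs for about 5% of null sequences.
#' Ties count as non-exceeding.
#'
#' @inheritParams g_statistic
#' @param trials number of Monte-Carlo trials (10,000 by default).
#' @param seed optional integer seed for reproducibility.
#' @return \code{f_G} in \eqn{[0, 1]}.
#' @seealso [w95()], [maxent_fit()]
#' @export
goodness_of_fit <- function(observed, dist, trials = 10000, seed = NULL) {
  stopifnot(inherits(dist, "maxent_dist"))
  if (length(trials) != 1L || trials < 1) stop("'trials' must be >= 1")
  v <- as_degree_values(observed)
  G_obs <- g_statistic(v, dist)
  set_seed_if_given(seed)
  G_null <- null_trial_stats(dist, length(v), as.integer(trials),
                             want_W = FALSE)$G
  mean(G_obs > G_null)
}

#' Relative width W of an observed degree distribution
#'
#' \eqn{W = \log(\sigma_O / \sigma_M)}: the log-ratio of the observed degree
#' sequence's standard deviation to the model's. Zero when the widths match;
#' negative when the observed distribution is narrower than the model.
#' Population standard deviations (divide by N) are used on both sides, so
#' the ratio compares like with like. A constant observed sequence
#' (\eqn{\sigma_O = 0}) returns \code{-Inf}, flagging a maximally narrow
#' distribution; a degenerate model (\eqn{\sigma_M = 0}) is an error.
#'
#' @inheritParams g_statistic
#' @return The scalar W (possibly \code{-Inf}).
#' @export
relative_width <- function(observed, dist) {
  stopifnot(inherits(dist, "maxent_dist"))
  sigma_M <- maxent_sd(dist)
  if (sigma_M == 0)
    stop("model distribution is degenerate (sigma_M = 0); W is undefined")
  sigma_O <- pop_sd(as_degree_values(observed))
  if (sigma_O == 0) return(-Inf)
  log(sigma_O / sigma_M)
}

#' Calibrated relative width W95
#'
#' Locates the observed relative width \eqn{W} within the null distribution
#' of \eqn{W} obtained from Monte-Carlo draws of same-length sequences from
#' the model. The deviation of the observed \eqn{W} from the null median is
#' normalized by the half-width of the null's central 95% interval on the
#' matching side:
#' \deqn{W_{95} = (W_{obs} - med) / (q_{97.5} - med) \quad if W_{obs} \ge med}
#' \deqn{W_{95} = (W_{obs} - med) / (med - q_{2.5}) \quad otherwise.}
#' Thus \eqn{W_{95} > 1} marks a distribution significantly broader than the
#' model at the 95% level and \eqn{W_{95} < -1} one significantly narrower;
#' by construction \eqn{|W_{95}| > 1} for about 5% of null sequences.
#' Quantiles use linear interpolation between order statistics. A constant
#' observed sequence propagates as \code{-Inf}.
#'
#' @inheritParams goodness_of_fit
#' @return The scalar \eqn{W_{95}} (possibly \code{-Inf}).
#' @export
w95 <- function(observed, dist, trials = 10000, seed = NULL) {
  stopifnot(inherits(dist, "maxent_dist"))
  if (length(trials) != 1L || trials < 1) stop("'trials' must be >= 1")
  v <- as_degree_values(observed)
  W_obs <- relative_width(v, dist)
  set_seed_if_given(seed)
  W_null <- null_trial_stats(dist, length(v), as.integer(trials),
                             want_G = FALSE)$W
  calibrate_w95(W_obs, W_null)
}

calibrate_w95 <- function(W_obs, W_null) {
  if (W_obs == -Inf) return(-Inf)
  med <- stats::median(W_null)
  q <- stats::quantile(W_null, c(0.025, 0.975), names = FALSE, type = 7)
  if (W_obs >= med) {
    half <- q[2] - med
    if (half <= 0) return(if (W_obs > med) Inf else 0)
    (W_obs - med) / half
  } else {
    half <- med - q[1]
    if (half <= 0) return(-Inf)
    (W_obs - med) / half
  }
}

#' Dual-criterion fit classification
#'
#' A degree distribution is considered well fit by the MaxEnt model only if
#' both the randomization test does not reject it (\code{f_G < 0.95}) and its
#' calibrated relative width is unremarkable (\code{-1 < W95 < 1}).
#'
#' @param f_G goodness of fit from [goodness_of_fit()].
#' @param W95 calibrated relative width from [w95()] (may be \code{-Inf} or
#'   \code{Inf}).
#' @return \code{TRUE} for a good fit, \code{FALSE} otherwise.
#' @export
classify_fit <- function(f_G, W95) {
  isTRUE(f_G < 0.95) && isTRUE(W95 > -1) && isTRUE(W95 < 1)
}

#' Full MaxEnt fit of one degree sequence
#'
#' Computes the observed G and W, then draws a single set of \code{trials}
#' null sequences from which both \code{f_G} and \code{W95} are calibrated,
#' and classifies the fit with the dual criterion. Using one shared null
#' ensemble for both statistics halves the simulation cost relative to
#' calling [goodness_of_fit()] and [w95()] separately and is statistically
#' equivalent, since each statistic is a functional of the same null.
#'
#' @inheritParams goodness_of_fit
#' @return An object of class \code{"maxent_fit"}: list with elements
#'   \code{f_G}, \code{W}, \code{W95}, \code{trials}, \code{seed} and
#'   \code{good_fit}.
#' @examples
#' d <- solve_maxent(20, 4)
#' x <- sample_degree_sequence(d, 30, seed = 1)
#' maxent_fit(x, d, trials = 1000, seed = 2)
#' @export
maxent_fit <- function(observed, dist, trials = 10000, seed = NULL) {
  stopifnot(inherits(dist, "maxent_dist"))
  if (length(trials) != 1L || trials < 1) stop("'trials' must be >= 1")
  v <- as_degree_values(observed)
  G_obs <- g_statistic(v, dist)
  W_obs <- relative_width(v, dist)
  set_seed_if_given(seed)
  nul <- null_trial_stats(dist, length(v), as.integer(trials))
  f_G <- mean(G_obs > nul$G)
  W95 <- calibrate_w95(W_obs, nul$W)
  structure(list(f_G = f_G, W = W_obs, W95 = W95,
                 trials = as.integer(trials),
                 seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
                 good_fit = classify_fit(f_G, W95)),
            class = "maxent_fit")
}

#' @export
print.maxent_fit <- function(x, ...) {
  cat(sprintf("MaxEnt fit: f_G = %.4f, W = %.4g, W95 = %.4g -> %s (%d trials)\n",
              x$f_G, x$W, x$W95,
              if (x$good_fit) "good fit" else "poor fit", x$trials))
  invisible(x)
}
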