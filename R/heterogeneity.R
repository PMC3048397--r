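#' Specify a heterogeneous coupled-subweb system
#'
#' Parameters for the heterogeneous-system degree-distribution model: a
#' sub-network of \code{sub_SA} animals and \code{sub_SP} plants with target
#' connectance \code{sub_CB} and a MaxEnt animal degree distribution is
#' drawn once, copied, and the copies are joined by sharing their most
#' general animal(s). With the default two copies and one shared generalist
#' the merged system has \code{2 * sub_SA - 1} animals and
#' \code{2 * sub_SP} plants. \code{k_subwebs >= 2} copies and
#' \code{m_shared >= 1} shared generalists are supported as a
#' generalization; the merged system then has
#' \code{k * sub_SA - (k - 1) * m} animals and \code{k * sub_SP} plants.
#'
#' This emulates a spatially or temporally heterogeneous community: several
#' internally well-connected sub-communities tied together only by one
#' super-generalist pollinator.
#'
#' @param sub_SA,sub_SP animals and plants per sub-web (both >= 2).
#' @param sub_CB target sub-web connectance, in \code{[1/sub_SP, 1]}.
#' @param k_subwebs number of identical sub-web copies (default 2).
#' @param m_shared number of shared generalist animals (default 1).
#' @param iterations Monte-Carlo iterations for [evaluate_coupled()].
#' @param trials null-model trials per iteration for f_G and W95.
#' @param seed optional integer master seed.
#' @return A list of class \code{"coupled_spec"}.
#' @export
coupled_spec <- function(sub_SA = 20, sub_SP = 20, sub_CB = 0.25,
                         k_subwebs = 2, m_shared = 1,
                         iterations = 100, trials = 10000, seed = NULL) {
  stopifnot(sub_SA >= 2, sub_SP >= 2, k_subwebs >= 2,
            m_shared >= 1, m_shared <= sub_SA, iterations >= 1, trials >= 1)
  mu_sub <- sub_CB * sub_SP
  if (mu_sub < 1 || mu_sub > sub_SP)
    stop(sprintf("sub_CB * sub_SP = %g outside [1, sub_SP]; sub-web mean degree infeasible",
                 mu_sub))
  structure(list(sub_SA = as.integer(sub_SA), sub_SP = as.integer(sub_SP),
                 sub_CB = sub_CB, k_subwebs = as.integer(k_subwebs),
                 m_shared = as.integer(m_shared),
                 iterations = as.integer(iterations),
                 trials = as.integer(trials), seed = seed),
            class = "coupled_spec")
}

#' Merged animal degree sequence of a coupled system
#'
#' Draws ONE sub-web animal degree sequence of length \code{sub_SA} from the
#' MaxEnt distribution on \code{1:sub_SP} with mean \code{sub_CB * sub_SP},
#' replicates it across the \code{k} identical sub-web copies, and merges
#' the copies' most general animals: the j-th most general animal of each
#' copy (j = 1..m_shared) becomes a single shared animal whose degree is the
#' sum over copies, i.e. \code{k * d_(j)}. Its plant partners are disjoint
#' across copies, so plant degrees are unchanged by the merge and the total
#' link count is exactly \code{k} times the sub-web's. Ties among maximal
#' degrees are broken by position; since the copies are identical, any
#' consistent rule yields the same merged multiset.
#'
#' @param spec a [coupled_spec()].
#' @param seed optional integer seed (overrides \code{spec$seed}).
#' @return A [degree_sequence()] of length
#'   \code{k * sub_SA - (k - 1) * m_shared} whose values sum to \code{k}
#'   times the realized sub-web link count.
#' @export
build_coupled_animal_sequence <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "coupled_spec"))
  set_seed_if_given(if (is.null(seed)) spec$seed else seed)
  build_merged_unseeded(spec)
}

# One merged draw using the current RNG state (no re-seeding): used inside
# the evaluate_coupled() loop, which seeds once up front.
build_merged_unseeded <- function(spec) {
  dist <- solve_maxent(spec$sub_SP, spec$sub_CB * spec$sub_SP)
  sub <- as.integer(sample_degree_sequence(dist, spec$sub_SA))
  merge_copies(sub, spec$k_subwebs, spec$m_shared)
}

# Pure merge rule on a sub-web degree sequence (exposed for direct tests).
merge_copies <- function(sub, k = 2L, m = 1L) {
  ord <- order(sub, decreasing = TRUE)
  shared <- k * sub[ord[seq_len(m)]]
  rest <- sub[ord[-seq_len(m)]]
  degree_sequence(c(rep(rest, k), shared), side = "animal")
}

#' Monte-Carlo evaluation of the coupled-system model against MaxEnt
#'
#' For each iteration a merged animal degree sequence is built with
#' [build_coupled_animal_sequence()] and then fitted against the MaxEnt null
#' a field worker would use for the merged network: support
#' \code{1:(k * sub_SP)} and mean equal to the realized merged link count
#' divided by the number of merged animals. f_G and W95 come from
#' [maxent_fit()] with \code{spec$trials} null draws. The shared
#' super-generalist makes the merged distribution broader than any MaxEnt
#' null with the same size and links, so the model is expected to be
#' rejected with a strongly positive mean W95 even though every sub-web is
#' itself MaxEnt.
#'
#' @param spec a [coupled_spec()].
#' @param seed optional integer master seed (overrides \code{spec$seed}).
#' @return A list of class \code{"coupled_eval"}: \code{mean_W95},
#'   \code{sd_W95}, \code{fraction_fG_rejected} (share of iterations with
#'   \code{f_G >= 0.95}), plus the per-iteration vectors \code{W95} and
#'   \code{f_G} and the input specification object.
#' @export
evaluate_coupled <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "coupled_spec"))
  set_seed_if_given(if (is.null(seed)) spec$seed else seed)
  n_model <- spec$k_subwebs * spec$sub_SP
  W95 <- f_G <- numeric(spec$iterations)
  for (it in seq_len(spec$iterations)) {
    merged <- build_merged_unseeded(spec)
    mu <- sum(merged) / length(merged)
    dist <- solve_maxent(n_model, mu)
    fit <- maxent_fit(merged, dist, trials = spec$trials)
    W95[it] <- fit$W95
    f_G[it] <- fit$f_G
  }
  structure(list(mean_W95 = mean(W95), sd_W95 = stats::sd(W95),
                 fraction_fG_rejected = mean(f_G >= 0.95),
                 W95 = W95, f_G = f_G, spec = spec),
            class = "coupled_eval")
}

#' @export
print.coupled_eval <- function(x, ...) {
  s <- x$spec
  cat(sprintf("Coupled-subweb evaluation (%d x [S_A = %d, S_P = %d, C_B = %g], %d iterations):\n",
              s$k_subwebs, s$sub_SA, s$sub_SP, s$sub_CB, s$iterations))
  cat(sprintf("  mean W95 = %.3f (sd %.3f), f_G rejection fraction = %.3f\n",
              x$mean_W95, x$sd_W95, x$fraction_fG_rejected))
  invisible(x)
}
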