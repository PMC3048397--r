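#' Generate a synthetic bipartite network
#'
#' Builds an explicit link set whose animal-side degree structure follows a
#' chosen statistical regime, so every stage of the fitting pipeline can be
#' exercised with known ground truth:
#'
#' \describe{
#'   \item{\code{maxent_null}}{animal degrees drawn from the MaxEnt
#'     distribution on \code{1:S_P} with mean \code{C_B * S_P}; each
#'     animal's links go to distinct plants chosen uniformly at random. The
#'     plant-side degree structure is emergent, not separately controlled
#'     (transpose the network to control the plant side instead).}
#'   \item{\code{hub_injected}}{a \code{maxent_null} web plus one extra
#'     super-generalist animal linked to a fraction
#'     \code{hub_degree_fraction} (default 0.8) of all plants — the
#'     single-dominant-pollinator structure seen in some large empirical
#'     webs.}
#'   \item{\code{truncated_narrow}}{as \code{maxent_null} but degrees above
#'     the \code{truncation_quantile} (default 0.9) of the null pmf are
#'     redrawn from below it, narrowing the distribution.}
#'   \item{\code{coupled_subwebs}}{an explicit graph realization of the
#'     heterogeneous coupled-subweb model (see [coupled_spec()]):
#'     \code{k_subwebs} identical sub-webs on disjoint plant sets joined by
#'     \code{m_shared} shared generalist animals; \code{S_A}, \code{S_P}
#'     and \code{C_B} here are the PER-SUBWEB parameters.}
#'   \item{\code{random_binomial}}{every (plant, animal) pair linked
#'     independently with probability \code{C_B} — the classical random
#'     bipartite graph whose degrees are binomial, a contrast to the MaxEnt
#'     regime.}
#' }
#'
#' After link assignment, plants left with no links are handled by redrawing
#' the assignment (up to 100 attempts) and, failing that, dropped, with the
#' realized sizes recoverable via [network_properties()]; empirical
#' incidence matrices likewise only contain interacting taxa.
#'
#' @param S_A,S_P animal and plant counts (per sub-web for
#'   \code{coupled_subwebs}).
#' @param C_B target connectance in \code{[1/S_P, 1]}.
#' @param mode one of the regimes above.
#' @param mode_params optional named list: \code{hub_degree_fraction},
#'   \code{truncation_quantile}, \code{k_subwebs}, \code{m_shared}.
#' @param seed optional integer seed; generation is bit-reproducible given
#'   the seed.
#' @return A [bipartite_network()] with \code{provenance = "synthetic"}.
#' @examples
#' net <- generate_network(30, 30, 0.2, seed = 42)
#' network_properties(net)
#' @export
generate_network <- function(S_A, S_P, C_B, mode = c("maxent_null",
                             "hub_injected", "truncated_narrow",
                             "coupled_subwebs", "random_binomial"),
                             mode_params = list(), seed = NULL) {
  mode <- match.arg(mode)
  stopifnot(S_A >= 2, S_P >= 2, C_B > 0, C_B <= 1)
  if (mode != "random_binomial" && C_B < 1 / S_P)
    stop("C_B below 1/S_P: mean animal degree under 1 is infeasible")
  set_seed_if_given(seed)
  switch(mode,
    maxent_null = gen_maxent_null(S_A, S_P, C_B),
    hub_injected = gen_hub_injected(S_A, S_P, C_B, mode_params),
    truncated_narrow = gen_truncated(S_A, S_P, C_B, mode_params),
    coupled_subwebs = gen_coupled(S_A, S_P, C_B, mode_params),
    random_binomial = gen_binomial(S_A, S_P, C_B))
}

plant_labels <- function(S_P) sprintf("p%03d", seq_len(S_P))
animal_labels <- function(S_A) sprintf("a%03d", seq_len(S_A))

# Assign each animal j links to `degrees[j]` distinct plants, redrawing the
# whole assignment until every plant is covered (up to 100 attempts), then
# dropping still-unlinked plants.
assign_links <- function(degrees, S_P, plants = plant_labels(S_P),
                         animals = animal_labels(length(degrees))) {
  stopifnot(all(degrees <= S_P))
  for (attempt in 1:100) {
    tgt <- unlist(lapply(degrees, function(d) sample.int(S_P, d)))
    if (length(unique(tgt)) == S_P) break
  }
  links <- data.frame(plant = plants[tgt],
                      animal = rep(animals, degrees),
                      stringsAsFactors = FALSE)
  suppressWarnings(bipartite_network(links, plant_ids = plants,
                                     animal_ids = animals,
                                     provenance = "synthetic"))
}

gen_maxent_null <- function(S_A, S_P, C_B) {
  dist <- solve_maxent(S_P, C_B * S_P)
  degrees <- as.integer(sample_degree_sequence(dist, S_A))
  assign_links(degrees, S_P)
}

gen_hub_injected <- function(S_A, S_P, C_B, mp) {
  frac <- if (is.null(mp$hub_degree_fraction)) 0.8 else mp$hub_degree_fraction
  stopifnot(frac > 0, frac <= 1)
  base <- gen_maxent_null(S_A, S_P, C_B)
  hub_deg <- max(1L, as.integer(ceiling(frac * length(base$plant_ids))))
  hub_plants <- sample(base$plant_ids, hub_deg)
  hub_id <- "a_hub"
  bipartite_network(rbind(base$links,
                          data.frame(plant = hub_plants, animal = hub_id,
                                     stringsAsFactors = FALSE)),
                    provenance = "synthetic")
}

gen_truncated <- function(S_A, S_P, C_B, mp) {
  q <- if (is.null(mp$truncation_quantile)) 0.9 else mp$truncation_quantile
  stopifnot(q > 0, q < 1)
  dist <- solve_maxent(S_P, C_B * S_P)
  cap <- which(cumsum(dist$pmf) >= q)[1L]  # smallest degree with cdf >= q
  degrees <- as.integer(sample_degree_sequence(dist, S_A))
  while (any(degrees > cap))
    degrees[degrees > cap] <- sample.int(dist$n, sum(degrees > cap),
                                         replace = TRUE, prob = dist$pmf)
  assign_links(degrees, S_P)
}

gen_coupled <- function(S_A, S_P, C_B, mp) {
  k <- if (is.null(mp$k_subwebs)) 2L else as.integer(mp$k_subwebs)
  m <- if (is.null(mp$m_shared)) 1L else as.integer(mp$m_shared)
  stopifnot(k >= 2, m >= 1, m <= S_A)
  dist <- solve_maxent(S_P, C_B * S_P)
  sub <- as.integer(sample_degree_sequence(dist, S_A))
  ord <- order(sub, decreasing = TRUE)
  shared_idx <- ord[seq_len(m)]
  copies <- vector("list", k)
  for (cp in seq_len(k)) {
    plants <- sprintf("w%d_p%03d", cp, seq_len(S_P))
    animals <- sprintf("w%d_a%03d", cp, seq_len(S_A))
    animals[shared_idx] <- sprintf("shared_a%02d", seq_len(m))  # same id in every copy
    copies[[cp]] <- assign_links(sub, S_P, plants = plants,
                                 animals = animals)$links
  }
  bipartite_network(do.call(rbind, copies), provenance = "synthetic")
}

gen_binomial <- function(S_A, S_P, C_B) {
  m <- matrix(stats::rbinom(S_P * S_A, 1L, C_B), S_P, S_A,
              dimnames = list(plant_labels(S_P), animal_labels(S_A)))
  incidence_to_network(m, provenance = "synthetic")
}

#' Generate a layered synthetic food web
#'
#' A three-layer directed web for exercising [reduce_foodweb()]: basal taxa
#' (no outgoing consumption links), consumers that eat basal taxa and,
#' optionally, each other, and top consumers that eat only other consumers.
#' Each consumer is guaranteed at least one basal prey and each top
#' consumer at least one consumer prey. The ground-truth bipartite
#' reduction — the basal taxa with at least one consumer, their consumers,
#' and the links between them — is recorded by the generator in the
#' \code{"bipartite_truth"} attribute.
#'
#' @param n_basal,n_consumers,n_top layer sizes (\code{n_top} may be 0).
#' @param c_cb probability a consumer eats a given basal taxon.
#' @param c_cc probability a consumer eats another given consumer (0
#'   disables intra-layer links).
#' @param c_tc probability a top consumer eats a given consumer.
#' @param seed optional integer seed.
#' @return A data frame of directed links (\code{consumer},
#'   \code{resource}) with attribute \code{"bipartite_truth"}, itself a
#'   data frame (\code{plant}, \code{animal}).
#' @export
generate_foodweb <- function(n_basal, n_consumers, n_top = 0,
                             c_cb = 0.3, c_cc = 0.1, c_tc = 0.4,
                             seed = NULL) {
  stopifnot(n_basal >= 1, n_consumers >= 1, n_top >= 0)
  set_seed_if_given(seed)
  basal <- sprintf("b%03d", seq_len(n_basal))
  cons <- sprintf("c%03d", seq_len(n_consumers))
  top <- if (n_top > 0) sprintf("t%03d", seq_len(n_top)) else character()

  pick <- function(pool, p) pool[stats::runif(length(pool)) < p]
  links <- list()
  for (cc in cons) {
    prey_b <- pick(basal, c_cb)
    if (!length(prey_b)) prey_b <- sample(basal, 1L)
    prey_c <- pick(setdiff(cons, cc), c_cc)
    links[[cc]] <- data.frame(consumer = cc, resource = c(prey_b, prey_c),
                              stringsAsFactors = FALSE)
  }
  for (tt in top) {
    prey_c <- pick(cons, c_tc)
    if (!length(prey_c)) prey_c <- sample(cons, 1L)
    links[[tt]] <- data.frame(consumer = tt, resource = prey_c,
                              stringsAsFactors = FALSE)
  }
  web <- do.call(rbind, links)
  rownames(web) <- NULL
  truth <- web[web$resource %in% basal, ]
  truth <- data.frame(plant = truth$resource, animal = truth$consumer,
                      stringsAsFactors = FALSE)
  attr(web, "bipartite_truth") <- truth[order(truth$plant, truth$animal), ]
  web
}
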