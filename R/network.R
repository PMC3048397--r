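#' Construct a bipartite network
#'
#' A bipartite ecological network: plant (resource) taxa, animal (consumer)
#' taxa, and undirected links between the two groups only. Every taxon kept
#' in the network participates in at least one link, matching the convention
#' that degree distributions start at degree 1; any listed taxon without a
#' link is dropped with a warning.
#'
#' @param links a two-column data frame (or matrix) of links with plant
#'   labels in the first column and animal labels in the second. Duplicate
#'   links are collapsed.
#' @param plant_ids,animal_ids optional label universes; defaults are the
#'   labels appearing in \code{links}.
#' @param provenance one of \code{"mutualistic"}, \code{"antagonistic"},
#'   \code{"synthetic"}.
#' @return An object of class \code{"bipartite_network"}: list with
#'   \code{plant_ids}, \code{animal_ids}, \code{links} (data frame with
#'   columns \code{plant}, \code{animal}) and \code{provenance}.
#' @seealso [network_properties()], [degree_sequences()], [read_incidence()]
#' @export
bipartite_network <- function(links, plant_ids = NULL, animal_ids = NULL,
                              provenance = c("synthetic", "mutualistic",
                                             "antagonistic")) {
  provenance <- match.arg(provenance)
  links <- as.data.frame(links, stringsAsFactors = FALSE)
  if (ncol(links) < 2L || nrow(links) < 1L)
    stop("'links' must have two columns (plant, animal) and at least one row")
  links <- data.frame(plant = as.character(links[[1L]]),
                      animal = as.character(links[[2L]]),
                      stringsAsFactors = FALSE)
  links <- unique(links)
  both <- intersect(unique(links$plant), unique(links$animal))
  if (length(both))
    stop("bipartite violation: label(s) on both sides: ",
         paste(utils::head(both, 5L), collapse = ", "))
  if (is.null(plant_ids)) plant_ids <- sort(unique(links$plant))
  if (is.null(animal_ids)) animal_ids <- sort(unique(links$animal))
  plant_ids <- as.character(plant_ids)
  animal_ids <- as.character(animal_ids)
  if (!all(links$plant %in% plant_ids) || !all(links$animal %in% animal_ids))
    stop("links reference labels outside the declared taxa")
  unlinked_p <- setdiff(plant_ids, links$plant)
  unlinked_a <- setdiff(animal_ids, links$animal)
  if (length(unlinked_p) || length(unlinked_a)) {
    warning(sprintf("dropping %d plant and %d animal taxa with no links",
                    length(unlinked_p), length(unlinked_a)))
    plant_ids <- setdiff(plant_ids, unlinked_p)
    animal_ids <- setdiff(animal_ids, unlinked_a)
  }
  structure(list(plant_ids = plant_ids, animal_ids = animal_ids,
                 links = links, provenance = provenance),
            class = "bipartite_network")
}

#' Size and connectance of a bipartite network
#'
#' Returns the standard bipartite descriptors: \code{S_P} plants, \code{S_A}
#' animals, \code{S = S_P + S_A} taxa, \code{L} links and the bipartite
#' connectance \code{C_B = L / (S_A * S_P)}, the fraction of possible
#' plant-animal links that occur.
#'
#' @param net a [bipartite_network()].
#' @return A list with elements \code{S_P}, \code{S_A}, \code{S}, \code{L},
#'   \code{C_B}.
#' @export
network_properties <- function(net) {
  stopifnot(inherits(net, "bipartite_network"))
  S_P <- length(net$plant_ids)
  S_A <- length(net$animal_ids)
  L <- nrow(net$links)
  list(S_P = S_P, S_A = S_A, S = S_P + S_A, L = L, C_B = L / (S_A * S_P))
}

#' Plant- and animal-side degree sequences of a network
#'
#' The plant sequence has one entry per plant (its number of animal
#' partners, in \code{1:S_A}); the animal sequence one entry per animal
#' (in \code{1:S_P}). Both sequences sum to \code{L}.
#'
#' @param net a [bipartite_network()].
#' @return A list with components \code{plant} and \code{animal}, each a
#'   [degree_sequence()].
#' @export
degree_sequences <- function(net) {
  stopifnot(inherits(net, "bipartite_network"))
  pd <- table(factor(net$links$plant, levels = net$plant_ids))
  ad <- table(factor(net$links$animal, levels = net$animal_ids))
  list(plant = degree_sequence(as.integer(pd), side = "plant"),
       animal = degree_sequence(as.integer(ad), side = "animal"))
}

#' @export
print.bipartite_network <- function(x, ...) {
  p <- network_properties(x)
  cat(sprintf("Bipartite network (%s): S_P = %d, S_A = %d, L = %d, C_B = %.4g\n",
              x$provenance, p$S_P, p$S_A, p$L, p$C_B))
  invisible(x)
}

#' Incidence matrix of a bipartite network
#'
#' @param net a [bipartite_network()].
#' @return A 0/1 integer matrix with plants as rows and animals as columns,
#'   labelled by taxon ids.
#' @export
incidence_matrix <- function(net) {
  stopifnot(inherits(net, "bipartite_network"))
  m <- matrix(0L, length(net$plant_ids), length(net$animal_ids),
              dimnames = list(net$plant_ids, net$animal_ids))
  m[cbind(match(net$links$plant, net$plant_ids),
          match(net$links$animal, net$animal_ids))] <- 1L
  m
}
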