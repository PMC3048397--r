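#' Reduce a food web to its basal-consumer bipartite subgraph
#'
#' Food webs are not bipartite, but the primary producers and their direct
#' consumers form a natural bipartite counterpart to plant-animal mutualistic
#' networks. The reduction keeps only the basal taxa (plants and detritus),
#' the taxa that consume them, and the links between these two groups;
#' everything else is discarded.
#'
#' A taxon is basal iff it has no outgoing consumption links (it consumes
#' nothing), or is named in \code{detritus_labels} — detritus counts as a
#' basal node even in webs that record outflows from it. Cannibalistic
#' self-loops are ignored for basal detection and never appear in the
#' output. Consumers with no link to any basal taxon are dropped entirely
#' (degree distributions start at 1), as are basal taxa nobody consumes.
#'
#' @param links a two-column data frame (or matrix) of directed trophic
#'   links: consumer in the first column, resource in the second.
#' @param detritus_labels optional taxa to force onto the basal (plant) side.
#' @return A [bipartite_network()] with \code{provenance = "antagonistic"};
#'   plants are the consumed basal taxa, animals their consumers. An empty
#'   reduction raises an error of class \code{"bimaxent_empty_network"}.
#' @examples
#' web <- data.frame(consumer = c("c", "c", "b"), resource = c("a", "b", "a"))
#' reduce_foodweb(web)  # plants {a}; animals {b, c}; c -> b discarded
#' @export
reduce_foodweb <- function(links, detritus_labels = character()) {
  links <- as.data.frame(links, stringsAsFactors = FALSE)
  if (ncol(links) < 2L) stop("'links' must have columns (consumer, resource)")
  consumer <- as.character(links[[1L]])
  resource <- as.character(links[[2L]])
  keep <- consumer != resource  # drop cannibalism
  consumer <- consumer[keep]
  resource <- resource[keep]
  taxa <- union(consumer, resource)
  basal <- union(setdiff(taxa, unique(consumer)), as.character(detritus_labels))
  sel <- resource %in% basal & !(consumer %in% basal)
  if (!any(sel)) {
    cond <- structure(class = c("bimaxent_empty_network", "error", "condition"),
                      list(message = "food-web reduction yields an empty bipartite network",
                           call = sys.call()))
    stop(cond)
  }
  bipartite_network(data.frame(plant = resource[sel], animal = consumer[sel],
                               stringsAsFactors = FALSE),
                    provenance = "antagonistic")
}
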