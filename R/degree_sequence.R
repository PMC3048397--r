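#' Degree sequence for one side of a bipartite network
#'
#' A vector of per-taxon link counts for either the plant (resource) side or
#' the animal (consumer) side of a bipartite network. All values are positive
#' integers: only interacting taxa appear in a degree distribution, so the
#' support starts at 1.
#'
#' @param values positive integer link counts, length >= 1.
#' @param side \code{"plant"} or \code{"animal"}.
#' @return An integer vector of class \code{"degree_sequence"} with attribute
#'   \code{side}.
#' @export
degree_sequence <- function(values, side = c("animal", "plant")) {
  side <- match.arg(side)
  values <- as.integer(values)
  if (length(values) < 1L) stop("a degree sequence needs at least one taxon")
  if (anyNA(values) || any(values < 1L))
    stop("all degrees must be positive integers (unlinked taxa are excluded)")
  structure(values, side = side, class = "degree_sequence")
}

# Accept either a degree_sequence or a bare numeric vector of degrees.
as_degree_values <- function(x) {
  if (inherits(x, "degree_sequence")) return(as.integer(unclass(x)))
  v <- as.integer(x)
  if (length(v) < 1L || anyNA(v) || any(v < 1L))
    stop("degrees must be positive integers")
  v
}

#' @export
print.degree_sequence <- function(x, ...) {
  cat(sprintf("%s degree sequence: %d taxa, %d links, degrees %d..%d\n",
              attr(x, "side"), length(x), sum(x), min(x), max(x)))
  invisible(x)
}
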