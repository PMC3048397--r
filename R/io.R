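#' Read a bipartite network from an incidence matrix file
#'
#' Parses a CSV/TSV matrix with plants as rows and animals as columns;
#' nonzero entries become links (quantitative matrices are binarized at
#' \code{> 0}). A header row of animal labels and/or a first column of plant
#' labels are detected automatically: any non-numeric cell in the first
#' row/column marks it as labels. All-zero rows or columns are dropped with
#' a warning, since unlinked taxa carry no degree. Published matrices vary
#' in orientation; use \code{transpose = TRUE} when rows are animals.
#'
#' @param path file to read.
#' @param sep field separator; \code{NULL} (default) sniffs comma vs tab vs
#'   whitespace from the first line.
#' @param transpose if \code{TRUE}, the file's rows are animals.
#' @param provenance network type label, see [bipartite_network()].
#' @return A [bipartite_network()].
#' @examples
#' tf <- tempfile(fileext = ".csv")
#' writeLines(c("1,0", "1,1"), tf)
#' net <- read_incidence(tf)
#' network_properties(net)  # S_P = 2, S_A = 2, L = 3, C_B = 0.75
#' @export
read_incidence <- function(path, sep = NULL, transpose = FALSE,
                           provenance = "synthetic") {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty incidence matrix: ", path)
  if (is.null(sep)) {
    sep <- if (grepl(",", lines[1L])) "," else if (grepl("\t", lines[1L])) "\t" else ""
  }
  split1 <- function(x) {
    out <- if (identical(sep, "")) strsplit(trimws(x), "[[:space:]]+")[[1L]]
           else strsplit(x, sep, fixed = TRUE)[[1L]]
    trimws(out)
  }
  cells <- lapply(lines, split1)
  widths <- lengths(cells)
  is_num <- function(x) !is.na(suppressWarnings(as.numeric(x)))

  header <- !all(is_num(cells[[1L]]))
  if (header && length(cells) < 2L) stop("matrix has a header but no data rows")
  body <- if (header) cells[-1L] else cells
  if (length(unique(lengths(body))) != 1L)
    stop(sprintf("ragged rows in %s: widths %s", path,
                 paste(unique(widths), collapse = ", ")))
  rowlab <- !all(vapply(body, function(r) is_num(r[1L]), logical(1L)))
  row_names <- if (rowlab) vapply(body, `[`, "", 1L) else paste0("p", seq_along(body))
  if (rowlab) body <- lapply(body, `[`, -1L)
  ncols <- length(body[[1L]])
  col_names <- if (header) {
    h <- cells[[1L]]
    utils::tail(h, ncols)  # header may or may not carry a corner cell
  } else paste0("a", seq_len(ncols))
  if (length(col_names) != ncols)
    stop("header length does not match the number of data columns")

  m <- matrix(NA_real_, length(body), ncols)
  for (r in seq_along(body)) {
    vals <- suppressWarnings(as.numeric(body[[r]]))
    if (anyNA(vals)) {
      bad <- which(is.na(vals))[1L]
      stop(sprintf("non-numeric cell at data row %d, column %d of %s: '%s'",
                   r, bad, path, body[[r]][bad]))
    }
    m[r, ] <- vals
  }
  dimnames(m) <- list(row_names, col_names)
  if (transpose) m <- t(m)
  incidence_to_network(m, provenance = provenance)
}

# Shared finalization: binarize, drop empty rows/cols with a warning, build
# the link set.
incidence_to_network <- function(m, provenance = "synthetic") {
  b <- m > 0
  drop_r <- rowSums(b) == 0
  drop_c <- colSums(b) == 0
  if (any(drop_r) || any(drop_c)) {
    warning(sprintf("dropping %d all-zero row(s) and %d all-zero column(s)",
                    sum(drop_r), sum(drop_c)))
    b <- b[!drop_r, !drop_c, drop = FALSE]
  }
  if (!length(b) || !any(b)) stop("incidence matrix contains no links")
  idx <- which(b, arr.ind = TRUE)
  bipartite_network(data.frame(plant = rownames(b)[idx[, 1L]],
                               animal = colnames(b)[idx[, 2L]],
                               stringsAsFactors = FALSE),
                    provenance = provenance)
}

#' Write a bipartite network as an incidence matrix
#'
#' Canonical form: plants as labelled rows, animals as labelled columns,
#' 0/1 entries, header row included. [read_incidence()] round-trips this
#' output exactly.
#'
#' @param net a [bipartite_network()].
#' @param path output file path.
#' @param sep field separator.
#' @export
write_incidence <- function(net, path, sep = ",") {
  m <- incidence_matrix(net)
  utils::write.table(m, path, sep = sep, quote = FALSE,
                     row.names = TRUE, col.names = NA)
  invisible(path)
}

#' Read a bipartite network from a two-column edge list
#'
#' Each non-comment line holds one link: plant label, then animal label,
#' separated by whitespace, comma or tab. Duplicate lines collapse to a
#' single link. A label appearing in both columns is a bipartite violation
#' and raises an error.
#'
#' @param path file to read; lines starting with \code{#} are ignored.
#' @param provenance network type label.
#' @return A [bipartite_network()].
#' @export
read_edgelist <- function(path, provenance = "synthetic") {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) stop("empty edge list: ", path)
  parts <- strsplit(lines, "[,\t[:space:]]+")
  bad <- which(lengths(parts) != 2L)
  if (length(bad))
    stop(sprintf("edge list line %d does not have two fields", bad[1L]))
  bipartite_network(data.frame(plant = vapply(parts, `[`, "", 1L),
                               animal = vapply(parts, `[`, "", 2L),
                               stringsAsFactors = FALSE),
                    provenance = provenance)
}

#' Write a bipartite network as an edge list
#'
#' Canonical form: one "plant<TAB>animal" line per link, sorted, so writers
#' and readers round-trip bit-equal.
#'
#' @param net a [bipartite_network()].
#' @param path output file path.
#' @export
write_edgelist <- function(net, path) {
  stopifnot(inherits(net, "bipartite_network"))
  l <- net$links[order(net$links$plant, net$links$animal), ]
  writeLines(paste(l$plant, l$animal, sep = "\t"), path)
  invisible(path)
}
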