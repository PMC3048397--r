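#' Fit MaxEnt nulls to both sides of one network
#'
#' Fits the side-specific MaxEnt null models — plant side on support
#' \code{1:S_A} with mean \code{L/S_P}, animal side on support \code{1:S_P}
#' with mean \code{L/S_A} — and evaluates each observed degree sequence with
#' [maxent_fit()]. The record also carries the network descriptors and a
#' size class: \code{small} for \code{S < 135}, \code{large} for
#' \code{S > 140}, \code{excluded} for the gap in between (bipartite food
#' webs in published compilations do not exceed ~134 taxa, so cross-type
#' comparisons are restricted to similarly sized networks).
#'
#' @param net a [bipartite_network()].
#' @param name label for the record.
#' @param trials null-model trials per side.
#' @param seed optional integer seed.
#' @return A list of class \code{"survey_record"} with fields \code{name},
#'   \code{web_type}, \code{S}, \code{S_P}, \code{S_A}, \code{L},
#'   \code{C_B}, \code{size_class}, \code{plant_fit}, \code{animal_fit}.
#' @export
analyze_network <- function(net, name = "network", trials = 10000,
                            seed = NULL) {
  stopifnot(inherits(net, "bipartite_network"))
  p <- network_properties(net)
  ds <- degree_sequences(net)
  plant_dist <- solve_maxent(p$S_A, p$L / p$S_P)
  animal_dist <- solve_maxent(p$S_P, p$L / p$S_A)
  plant_fit <- maxent_fit(ds$plant, plant_dist, trials = trials, seed = seed)
  animal_fit <- maxent_fit(ds$animal, animal_dist, trials = trials,
                           seed = if (is.null(seed)) NULL else seed + 1L)
  structure(list(name = as.character(name), web_type = net$provenance,
                 S = p$S, S_P = p$S_P, S_A = p$S_A, L = p$L, C_B = p$C_B,
                 size_class = size_class(p$S),
                 plant_fit = plant_fit, animal_fit = animal_fit),
            class = "survey_record")
}

size_class <- function(S) {
  if (S < 135) "small" else if (S > 140) "large" else "excluded"
}

#' Survey a collection of networks
#'
#' Runs [analyze_network()] over a list of networks. Each network gets a
#' deterministic seed derived from the master seed and its name, so the
#' survey is reproducible and insensitive to processing order.
#'
#' @param nets named list of [bipartite_network()] objects (names label the
#'   records).
#' @param trials null-model trials per degree distribution.
#' @param seed master integer seed.
#' @return A list of \code{"survey_record"} objects, class
#'   \code{"survey_records"}.
#' @export
survey_networks <- function(nets, trials = 10000, seed = 1) {
  stopifnot(is.list(nets), length(nets) >= 1)
  nms <- names(nets)
  if (is.null(nms)) nms <- paste0("net", seq_along(nets))
  recs <- vector("list", length(nets))
  for (i in seq_along(nets)) {
    recs[[i]] <- analyze_network(nets[[i]], name = nms[i], trials = trials,
                                 seed = derive_seed(seed, nms[i]))
  }
  structure(recs, class = "survey_records")
}

#' Flatten survey records to a data frame
#'
#' One row per network and side, with columns \code{name}, \code{web_type},
#' \code{S}, \code{S_P}, \code{S_A}, \code{L}, \code{C_B},
#' \code{size_class}, \code{side}, \code{f_G}, \code{W}, \code{W95},
#' \code{good_fit}, \code{trials}, \code{seed}.
#'
#' @param x a \code{"survey_records"} list (or single record).
#' @param ... unused.
#' @export
as.data.frame.survey_records <- function(x, ...) {
  do.call(rbind, lapply(unclass(x), record_rows))
}

#' @export
as.data.frame.survey_record <- function(x, ...) record_rows(x)

record_rows <- function(r) {
  row1 <- function(side, fit) {
    data.frame(name = r$name, web_type = r$web_type, S = r$S, S_P = r$S_P,
               S_A = r$S_A, L = r$L, C_B = r$C_B, size_class = r$size_class,
               side = side, f_G = fit$f_G, W = fit$W, W95 = fit$W95,
               good_fit = fit$good_fit, trials = fit$trials, seed = fit$seed,
               stringsAsFactors = FALSE)
  }
  rbind(row1("plant", r$plant_fit), row1("animal", r$animal_fit))
}

#' Tabulate good-fit counts and fractions by stratum
#'
#' Cross-network summary in the style of a networks-by-type/size table:
#' for each stratum and each side, the number of networks, the number whose
#' degree distribution the MaxEnt model fits well (dual criterion,
#' [classify_fit()]), and the good-fit fraction. Empty strata are omitted.
#'
#' @param records a \code{"survey_records"} list.
#' @param stratify_by \code{"web_type"}, \code{"size_class"}, or both.
#' @return A data frame with columns \code{stratum}, \code{side}, \code{n},
#'   \code{good}, \code{fraction}.
#' @export
tabulate_fits <- function(records, stratify_by = c("web_type", "size_class")) {
  stratify_by <- match.arg(stratify_by, c("web_type", "size_class"),
                           several.ok = TRUE)
  df <- as.data.frame.survey_records(records)
  df$stratum <- do.call(paste, c(unname(df[stratify_by]), sep = ", "))
  out <- do.call(rbind, lapply(split(df, df[c("stratum", "side")], drop = TRUE),
    function(g) data.frame(stratum = g$stratum[1L], side = g$side[1L],
                           n = nrow(g), good = sum(g$good_fit),
                           fraction = mean(g$good_fit),
                           stringsAsFactors = FALSE)))
  rownames(out) <- NULL
  out[order(out$stratum, out$side), ]
}

#' Fisher's exact test for a 2x2 contingency table
#'
#' Exact two-tailed p-value for the table \code{rbind(c(a, b), c(c, d))},
#' via the sum-of-smaller-probabilities rule: all tables with the observed
#' margins whose hypergeometric probability does not exceed the observed
#' table's are summed. Used in cross-network comparisons, e.g. counts of
#' networks with few plant taxa, or good-fit counts across network types.
#'
#' @param a,b,c,d nonnegative integer cell counts (row1: a, b; row2: c, d).
#' @return The two-tailed p-value.
#' @examples
#' fisher_exact_2x2(19, 28, 7, 44)  # 0.0032: plant-poor antagonistic vs mutualistic webs
#' @export
fisher_exact_2x2 <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  if (any(cells < 0) || any(cells != round(cells)))
    stop("cell counts must be nonnegative integers")
  m <- matrix(as.integer(cells), nrow = 2, byrow = TRUE)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0))
    stop("a margin of the 2x2 table is zero; the test is undefined")
  stats::fisher.test(m, alternative = "two.sided")$p.value
}

#' Exact binomial sign test
#'
#' Tail probability for \code{k} successes in \code{n} trials at success
#' probability 1/2. Used for sign counts of W95 among poorly fit networks
#' (is an excess of broader-than-null distributions significant?). The
#' one-tailed version (upper tail, \eqn{P(X \ge k)}) is the default for such
#' directional sign counts; the two-tailed version doubles the smaller tail
#' and caps at 1.
#'
#' @param k number of successes, \code{0 <= k <= n}.
#' @param n number of trials.
#' @param tail \code{"one"} (default) or \code{"two"}.
#' @return The exact p-value.
#' @examples
#' binomial_sign_test(13, 17)  # 0.0245: 13 of 17 broader than the null
#' @export
binomial_sign_test <- function(k, n, tail = c("one", "two")) {
  tail <- match.arg(tail)
  stopifnot(length(k) == 1L, length(n) == 1L, k >= 0, k <= n, n >= 1)
  upper <- stats::pbinom(k - 1, n, 0.5, lower.tail = FALSE)  # P(X >= k)
  if (tail == "one") return(upper)
  lower <- stats::pbinom(k, n, 0.5)                          # P(X <= k)
  min(1, 2 * min(upper, lower))
}

#' Regress W95 on network size
#'
#' Ordinary least squares of the calibrated relative width against the
#' number of taxa \code{S}, per side and optionally per network type;
#' quantifies scale dependence of the deviation from the MaxEnt null.
#' Records with non-finite W95 are excluded. The slope p-value is two-sided
#' from the t distribution.
#'
#' @param records a \code{"survey_records"} list.
#' @param side \code{"plant"} or \code{"animal"}.
#' @param web_type optional filter (\code{"mutualistic"},
#'   \code{"antagonistic"}, \code{"synthetic"}).
#' @return A list with \code{slope}, \code{intercept}, \code{R2},
#'   \code{p_slope}, \code{n}.
#' @export
regress_w95_on_S <- function(records, side = c("plant", "animal"),
                             web_type = NULL) {
  side <- match.arg(side)
  df <- as.data.frame.survey_records(records)
  df <- df[df$side == side & is.finite(df$W95), ]
  if (!is.null(web_type)) df <- df[df$web_type == web_type, ]
  if (nrow(df) < 3) stop("need at least 3 records with finite W95")
  if (stats::var(df$S) == 0) stop("no variance in S; regression undefined")
  fit <- stats::lm(W95 ~ S, data = df)
  sm <- summary(fit)
  list(slope = unname(stats::coef(fit)[2L]),
       intercept = unname(stats::coef(fit)[1L]),
       R2 = sm$r.squared,
       p_slope = sm$coefficients["S", "Pr(>|t|)"],
       n = nrow(df))
}
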