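# Stringent filter for highly confident heterozygous calls on pileup base
# counts, and the cumulative depth curves used to compare heterozygous-call
# groups.

#' Highly confident heterozygous call criterion
#'
#' A site passes iff its total base count strictly exceeds `min_depth`
#' (default: more than 20x coverage) AND the second most frequent base
#' makes up strictly more than `min_second_fraction` of the total (default
#' >30%). With ties for the most frequent base the second-largest count
#' (with multiplicity) is used, the most permissive reading.
#'
#' @param counts numeric vector of 4 base counts, or a matrix/data.frame
#'   with columns A, C, G, T (one row per site).
#' @param min_depth strict lower bound on total coverage.
#' @param min_second_fraction strict lower bound on the second-base
#'   fraction.
#' @return logical vector, one element per site (`FALSE` for zero totals).
#' @export
is_confident_het <- function(counts, min_depth = 20L,
                             min_second_fraction = 0.30) {
  m <- if (is.null(dim(counts))) matrix(as.numeric(counts), nrow = 1)
       else as.matrix(counts[, DNA_BASES, drop = FALSE])
  if (ncol(m) != 4) stop("counts must have the four bases A, C, G, T")
  if (any(m < 0)) stop("negative base count")
  total <- rowSums(m)
  second <- apply(m, 1, function(r) sort(r, decreasing = TRUE)[2])
  total > min_depth & ifelse(total > 0, second / total, 0) >
    min_second_fraction
}

#' Fraction of sites passing the confident-het criterion
#'
#' @param counts matrix/data.frame of base counts (columns A, C, G, T).
#' @param ... passed to [is_confident_het()].
#' @return list: `n_confident`, `n_total`, `percent` (2 dp) and
#'   `percent_headline` (whole percent). `NA` percentages for empty input.
#' @export
confident_fraction <- function(counts, ...) {
  n <- if (is.null(dim(counts))) as.integer(length(counts) > 0)
       else nrow(counts)
  if (n == 0)
    return(list(n_confident = 0L, n_total = 0L, percent = NA_real_,
                percent_headline = NA_real_))
  ok <- is_confident_het(counts, ...)
  list(n_confident = sum(ok), n_total = n,
       percent = pct_of(sum(ok), n),
       percent_headline = round_half_up(100 * sum(ok) / n, 0))
}

#' Cumulative depth-frequency curves per group
#'
#' For each group of depths, the fraction of sites with depth <= d at every
#' integer d spanning the group's range; monotone non-decreasing and
#' reaching 1.
#'
#' @param groups named list of integer depth vectors (each nonempty).
#' @return `data.frame`: group, depth, cum_fraction.
#' @export
depth_cumulative_curve <- function(groups) {
  stopifnot(is.list(groups), length(groups) > 0, !is.null(names(groups)))
  out <- lapply(names(groups), function(g) {
    d <- groups[[g]]
    if (length(d) == 0) stop("empty depth group: ", g)
    dd <- seq.int(min(d), max(d))
    data.frame(group = g, depth = dd,
               cum_fraction = stats::ecdf(d)(dd),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
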