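# Per-base callability classification (callable / poor mapping quality /
# low coverage / no coverage), run-length encoded tracks, multi-platform
# merging, interval export and base composition of non-callable regions.

CALLABILITY_STATES <- c("CALLABLE", "POOR_MQ", "LOW_COVERAGE", "NO_COVERAGE")

#' Callability thresholds
#'
#' Defaults mirror the standard CallableLoci settings: minimum depth 4 and
#' minimum mapping quality 10, both inclusive ("minimum equal to").
#'
#' @param min_depth integer >= 1.
#' @param min_mq number >= 0.
#' @return a `callability_thresholds` list.
#' @export
callability_thresholds <- function(min_depth = 4L, min_mq = 10) {
  if (min_depth < 1) stop("min_depth must be >= 1")
  if (min_mq < 0) stop("min_mq must be >= 0")
  structure(list(min_depth = as.integer(min_depth), min_mq = min_mq),
            class = "callability_thresholds")
}

#' Classify bases by depth and mapping quality
#'
#' Coverage is evaluated before mapping quality: depth 0 is `NO_COVERAGE`;
#' positive depth below `min_depth` is `LOW_COVERAGE` (regardless of MQ);
#' sufficient depth with MQ below `min_mq` is `POOR_MQ`; otherwise
#' `CALLABLE`. Both thresholds are inclusive.
#'
#' @param depth,mq numeric vectors (recycled to common length).
#' @param thresholds a [callability_thresholds()].
#' @return character vector of states.
#' @export
classify_base <- function(depth, mq, thresholds = callability_thresholds()) {
  if (any(depth < 0, na.rm = TRUE)) stop("negative depth")
  n <- max(length(depth), length(mq))
  depth <- rep_len(depth, n); mq <- rep_len(mq, n)
  ifelse(depth == 0, "NO_COVERAGE",
         ifelse(depth < thresholds$min_depth, "LOW_COVERAGE",
                ifelse(mq < thresholds$min_mq, "POOR_MQ", "CALLABLE")))
}

#' Build a run-length encoded callability track
#'
#' @param depth,mq `per_base_track`s over the same contig spans.
#' @param thresholds a [callability_thresholds()].
#' @return a `callability_track`: list with `runs` (per contig, an [rle()]
#'   of states) and `seqlengths`.
#' @export
build_track <- function(depth, mq, thresholds = callability_thresholds()) {
  if (!identical(depth$seqlengths, mq$seqlengths))
    stop("depth and MQ tracks cover different spans")
  runs <- lapply(names(depth$seqlengths), function(ctg)
    rle(classify_base(depth$values[[ctg]], mq$values[[ctg]], thresholds)))
  names(runs) <- names(depth$seqlengths)
  structure(list(runs = runs, seqlengths = depth$seqlengths),
            class = "callability_track")
}

#' Decode a callability track to per-base states
#'
#' @param track a `callability_track`.
#' @param contig contig name.
#' @return character vector of states, one per base.
#' @export
decode_track <- function(track, contig) inverse.rle(track$runs[[contig]])

# total bases per state across all contigs
state_base_counts <- function(track) {
  out <- stats::setNames(numeric(length(CALLABILITY_STATES)),
                         CALLABILITY_STATES)
  for (r in track$runs)
    for (s in unique(r$values))
      out[s] <- out[s] + sum(r$lengths[r$values == s])
  out
}

#' Fraction of the genome in given callability states
#'
#' @param track a `callability_track`.
#' @param states states of interest (default `"CALLABLE"`; the secondary
#'   headline including poorly mapped bases uses
#'   `c("CALLABLE", "POOR_MQ")`).
#' @return percentage of all bases, 2 dp.
#' @export
callability_fraction <- function(track, states = "CALLABLE") {
  stopifnot(all(states %in% CALLABILITY_STATES))
  counts <- state_base_counts(track)
  pct_of(sum(counts[states]), sum(counts))
}

#' Merge two platforms' coverage and classify the combined data
#'
#' Per base, merged depth is the sum of the two depths and merged MQ the
#' depth-weighted mean of the two MQs (a platform with zero depth
#' contributes nothing); [classify_base()] is then applied to the merged
#' values. Approximates classifying a merged alignment.
#'
#' @param depth1,mq1,depth2,mq2 `per_base_track`s over the same spans.
#' @param thresholds a [callability_thresholds()].
#' @return a `callability_track` for the merged data.
#' @export
merge_tracks <- function(depth1, mq1, depth2, mq2,
                         thresholds = callability_thresholds()) {
  if (!identical(depth1$seqlengths, depth2$seqlengths))
    stop("platform tracks cover different spans")
  lens <- depth1$seqlengths
  dv <- list(); mv <- list()
  for (ctg in names(lens)) {
    d1 <- depth1$values[[ctg]]; d2 <- depth2$values[[ctg]]
    m1 <- mq1$values[[ctg]]; m2 <- mq2$values[[ctg]]
    d <- d1 + d2
    m <- ifelse(d > 0, (d1 * m1 + d2 * m2) / pmax(d, 1), 0)
    dv[[ctg]] <- d; mv[[ctg]] <- m
  }
  build_track(structure(list(values = dv, seqlengths = lens),
                        class = "per_base_track"),
              structure(list(values = mv, seqlengths = lens),
                        class = "per_base_track"),
              thresholds)
}

#' Base composition of non-callable regions
#'
#' Composition of the reference sequence over every position whose state is
#' not `CALLABLE`. A/C/G/T fractions sum to 1 over non-N bases; N bases are
#' counted separately.
#'
#' @param track a `callability_track`.
#' @param reference a `DNAStringSet` covering the track's contigs.
#' @return list: `fractions` (named A/C/G/T, `NA` if no non-callable
#'   bases), `counts`, `n_bases` and `n_N`.
#' @export
noncallable_base_composition <- function(track, reference) {
  counts <- stats::setNames(numeric(4), DNA_BASES); nN <- 0
  for (ctg in names(track$runs)) {
    if (!ctg %in% names(reference))
      stop("contig absent from reference: ", ctg)
    r <- track$runs[[ctg]]
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    sel <- r$values != "CALLABLE"
    if (!any(sel)) next
    v <- Biostrings::Views(reference[[ctg]],
                           start = starts[sel], end = ends[sel])
    lf <- Biostrings::letterFrequency(v, c(DNA_BASES, "N"))
    tot <- colSums(lf)
    counts <- counts + tot[DNA_BASES]
    nN <- nN + tot[["N"]]
  }
  n <- sum(counts)
  list(fractions = if (n > 0) counts / n else
         stats::setNames(rep(NA_real_, 4), DNA_BASES),
       counts = counts, n_bases = n, n_N = nN)
}

#' Export maximal intervals of one state as regions
#'
#' @param track a `callability_track`.
#' @param state a callability state.
#' @return `GRanges` of maximal runs in that state (1-based in memory;
#'   [write_bed()] emits standard 0-based half-open BED).
#' @export
export_regions <- function(track, state) {
  stopifnot(state %in% CALLABILITY_STATES)
  ctg <- character(0); s <- integer(0); e <- integer(0)
  for (nm in names(track$runs)) {
    r <- track$runs[[nm]]
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    sel <- r$values == state
    ctg <- c(ctg, rep(nm, sum(sel)))
    s <- c(s, starts[sel]); e <- c(e, ends[sel])
  }
  gr <- GenomicRanges::GRanges(
    seqnames = factor(ctg, levels = names(track$runs)),
    ranges = IRanges::IRanges(start = s, end = e),
    seqlengths = track$seqlengths)
  normalize_regions(gr, merge = FALSE)
}

# per-base state at given sites (for chip-concordance by callability)
track_state_at <- function(track, contig, pos) {
  mapply(function(ctg, p) {
    r <- track$runs[[ctg]]
    idx <- findInterval(p, cumsum(r$lengths) - r$lengths + 1L)
    r$values[idx]
  }, contig, pos, USE.NAMES = FALSE)
}
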