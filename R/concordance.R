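# Three-way classification of SNVs between two platforms, and the
# zygosity / repeat-overlap summaries computed on the classified records.

CONCORDANCE_CATEGORIES <- c("CONCORDANT", "DISCORDANT",
                            "P1_SPECIFIC", "P2_SPECIFIC")

#' Classify sites between two platform call sets
#'
#' Every site present in either call set lands in exactly one category:
#' `CONCORDANT` (called in both with identical alt allele and zygosity),
#' `DISCORDANT` (called in both, differing zygosity or alt; alt
#' disagreement is flagged in `alt_mismatch`), or `P1_SPECIFIC` /
#' `P2_SPECIFIC` (called in exactly one platform).
#'
#' @param p1,p2 variant-call `data.frame`s (see [variant_calls()]), at most
#'   one record per site each.
#' @return a `data.frame` of concordance records: key, contig, pos, ref,
#'   category, zygosity/alt/depth per platform (`"ABSENT"`/`NA` where
#'   uncalled) and `alt_mismatch`.
#' @export
classify_sites <- function(p1, p2) {
  for (nm in c("p1", "p2")) {
    x <- get(nm)
    if (anyDuplicated(x$key))
      stop("duplicate site within ", nm, ": ",
           paste(utils::head(unique(x$key[duplicated(x$key)]), 3),
                 collapse = ", "))
  }
  keys <- union(p1$key, p2$key)
  i1 <- match(keys, p1$key); i2 <- match(keys, p2$key)
  in1 <- !is.na(i1); in2 <- !is.na(i2)
  ref <- ifelse(in1, p1$ref[i1], p2$ref[i2])
  both <- in1 & in2
  if (any(both & p1$ref[i1] != p2$ref[i2], na.rm = TRUE))
    stop("reference allele disagrees between platforms at shared site(s)")
  zyg1 <- ifelse(in1, p1$zygosity[i1], "ABSENT")
  zyg2 <- ifelse(in2, p2$zygosity[i2], "ABSENT")
  alt1 <- ifelse(in1, p1$alt[i1], NA_character_)
  alt2 <- ifelse(in2, p2$alt[i2], NA_character_)
  same <- both & alt1 == alt2 & zyg1 == zyg2
  category <- ifelse(both, ifelse(same, "CONCORDANT", "DISCORDANT"),
                     ifelse(in1, "P1_SPECIFIC", "P2_SPECIFIC"))
  contig <- ifelse(in1, p1$contig[i1], p2$contig[i2])
  pos <- ifelse(in1, p1$pos[i1], p2$pos[i2])
  out <- data.frame(
    key = keys, contig = contig, pos = as.integer(pos), ref = ref,
    category = category,
    zygosity_p1 = zyg1, zygosity_p2 = zyg2,
    alt_p1 = alt1, alt_p2 = alt2,
    depth_p1 = ifelse(in1, p1$depth[i1], NA_integer_),
    depth_p2 = ifelse(in2, p2$depth[i2], NA_integer_),
    alt_mismatch = both & alt1 != alt2,
    stringsAsFactors = FALSE
  )
  out <- out[order(out$contig, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Tabulate concordance categories
#'
#' @param records output of [classify_sites()].
#' @return named integer vector over the four categories.
#' @export
concordance_counts <- function(records) {
  vapply(CONCORDANCE_CATEGORIES,
         function(k) sum(records$category == k), integer(1))
}

# zygosity column relevant for a (category, platform) selection
zygosity_for <- function(records, category, platform = NULL) {
  if (is.null(platform))
    platform <- switch(category,
                       P1_SPECIFIC = "p1", P2_SPECIFIC = "p2",
                       CONCORDANT = "p1",
                       stop("platform must be given for category ", category))
  records[records$category == category, paste0("zygosity_", platform)]
}

#' Heterozygosity rate of a concordance category
#'
#' Percentage of sites in the category that are heterozygous, on the named
#' platform's calls (for `CONCORDANT` both platforms agree; for the
#' `*_SPECIFIC` categories the calling platform is implied).
#'
#' @param records output of [classify_sites()].
#' @param category one of the four category labels.
#' @param platform `"p1"` or `"p2"`; required for `DISCORDANT`.
#' @return percentage rounded to 2 dp, or `NA` for an empty category.
#' @export
heterozygosity_rate <- function(records, category, platform = NULL) {
  z <- zygosity_for(records, category, platform)
  if (length(z) == 0) return(NA_real_)
  pct_of(sum(z == "HET"), length(z))
}

#' Fraction of a category's sites inside repeat regions
#'
#' A 1-based site position p is inside a BED interval `[start, end)` iff its
#' 0-based offset p-1 falls in it, i.e. ordinary 1-based interval overlap.
#'
#' @param records output of [classify_sites()].
#' @param category category label.
#' @param repeats a normalized `GRanges` of repeat regions.
#' @return percentage rounded to 2 dp, or `NA` for an empty category.
#' @export
repeat_overlap <- function(records, category, repeats) {
  sel <- records[records$category == category, , drop = FALSE]
  if (nrow(sel) == 0) return(NA_real_)
  gr <- GenomicRanges::GRanges(sel$contig, IRanges::IRanges(sel$pos, sel$pos))
  pct_of(sum(IRanges::overlapsAny(gr, repeats)), nrow(sel))
}
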