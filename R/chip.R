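# Chip-concordance: comparison of sequencing genotypes with SNP-chip
# genotypes, incorporating the reference base (a sequencing call implies
# the unordered genotype {alt,alt} if HOM, {ref,alt} if HET).

#' Chip status of sequencing calls
#'
#' For each call, looks up the chip genotype at the same site and compares
#' unordered genotypes. Sites absent from the chip are `NOT_ON_CHIP`. A
#' chip genotype homozygous for the reference base contradicts any
#' sequencing variant call and is `CHIP_DISCORDANT`, flagged in
#' `chip_hom_ref`.
#'
#' @param calls a variant-call `data.frame` (or any `data.frame` with key,
#'   ref, alt, zygosity columns).
#' @param chip output of [read_chip()] / [simulate_chip()].
#' @param reference a `DNAStringSet`; each call's ref allele is checked
#'   against it (mismatch is an error).
#' @return `data.frame`: key, status (`CHIP_CONCORDANT` /
#'   `CHIP_DISCORDANT` / `NOT_ON_CHIP`), chip_zygosity (`NA` when not on
#'   chip) and chip_hom_ref.
#' @export
chip_status <- function(calls, chip, reference = NULL) {
  if (!is.null(reference)) {
    for (ctg in unique(calls$contig)) {
      if (!ctg %in% names(reference))
        stop("contig absent from reference: ", ctg)
      sel <- calls$contig == ctg
      rb <- as.character(
        Biostrings::extractAt(reference[[ctg]],
                              IRanges::IRanges(calls$pos[sel],
                                               calls$pos[sel])))
      bad <- which(rb != calls$ref[sel])
      if (length(bad))
        stop("reference mismatch at ", calls$key[sel][bad[1]],
             ": call ref ", calls$ref[sel][bad[1]], ", reference ",
             rb[bad[1]])
    }
  }
  i <- match(calls$key, chip$key)
  on_chip <- !is.na(i)
  seq_a <- ifelse(calls$zygosity == "HOM", calls$alt, calls$ref)
  seq_lo <- pmin(seq_a, calls$alt); seq_hi <- pmax(seq_a, calls$alt)
  chip_lo <- pmin(chip$allele_a[i], chip$allele_b[i])
  chip_hi <- pmax(chip$allele_a[i], chip$allele_b[i])
  conc <- on_chip & seq_lo == chip_lo & seq_hi == chip_hi
  data.frame(
    key = calls$key,
    status = ifelse(!on_chip, "NOT_ON_CHIP",
                    ifelse(conc, "CHIP_CONCORDANT", "CHIP_DISCORDANT")),
    chip_zygosity = ifelse(on_chip,
                           ifelse(chip_lo == chip_hi, "HOM", "HET"),
                           NA_character_),
    chip_hom_ref = on_chip & chip_lo == chip_hi & chip_lo == calls$ref,
    stringsAsFactors = FALSE
  )
}

#' Chip-concordance rate
#'
#' `100 * n_concordant / (n_concordant + n_discordant)`, rounded half away
#' from zero to 2 dp. Sites not on the chip are excluded from both counts
#' by the callers of this function.
#'
#' @param n_concordant,n_discordant non-negative counts (vectorized).
#' @return percentage, `NA` where the denominator is zero.
#' @export
concordance_rate <- function(n_concordant, n_discordant) {
  pct_of(n_concordant, n_concordant + n_discordant)
}

#' Chip-discordance pattern matrix
#'
#' The 2x2 cross-tabulation of chip zygosity against sequencing zygosity
#' over chip-discordant sites, with each cell also expressed as a
#' percentage of the grand total.
#'
#' @param chip_zygosity,seq_zygosity character vectors of `"HOM"`/`"HET"`,
#'   one element per site.
#' @return list with `counts` and `percent` (2x2 matrices, rows = chip
#'   zygosity, columns = sequencing zygosity) and `total`.
#' @export
pattern_matrix <- function(chip_zygosity, seq_zygosity) {
  stopifnot(length(chip_zygosity) == length(seq_zygosity))
  lv <- c("HOM", "HET")
  if (!all(chip_zygosity %in% lv) || !all(seq_zygosity %in% lv))
    stop("zygosity values must be HOM or HET")
  counts <- table(factor(chip_zygosity, lv), factor(seq_zygosity, lv))
  counts <- matrix(as.integer(counts), 2, 2,
                   dimnames = list(chip = lv, sequencing = lv))
  total <- sum(counts)
  percent <- if (total > 0) round_half_up(100 * counts / total)
             else counts * NA_real_
  list(counts = counts, percent = percent, total = total)
}

#' Median sequencing depth
#'
#' Middle element for odd n; arithmetic mean of the two middle elements for
#' even n (so half-integer medians such as 10.5 can occur).
#'
#' @param depths integer vector.
#' @return the median, `NA` for an empty vector.
#' @export
median_depth <- function(depths) {
  depths <- depths[!is.na(depths)]
  if (length(depths) == 0) return(NA_real_)
  as.numeric(stats::median(depths))
}
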