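# Readers and writers for the external formats, and the single home for the
# coordinate/allele conventions (VCF and internal keys 1-based; BED and
# bedGraph 0-based half-open on disk).

#' Construct a variant-call table
#'
#' The in-memory representation of a single-sample SNV call set: one row per
#' site with single-base ref/alt alleles, a diploid zygosity and a read
#' depth.
#'
#' @param contig character vector of contig names.
#' @param pos integer vector of 1-based positions.
#' @param ref,alt single-base alleles (A/C/G/T), `ref != alt` row-wise.
#' @param zygosity `"HOM"` or `"HET"`.
#' @param depth non-negative integer read depth (0 when unknown).
#' @return a `data.frame` with those columns plus a `key` column
#'   (`"contig:pos"`), ordered by contig then position.
#' @export
variant_calls <- function(contig, pos, ref, alt, zygosity, depth = 0L) {
  n <- length(contig)
  df <- data.frame(
    contig = as.character(contig), pos = as.integer(pos),
    ref = toupper(as.character(ref)), alt = toupper(as.character(alt)),
    zygosity = as.character(zygosity),
    depth = rep_len(as.integer(depth), n),
    stringsAsFactors = FALSE
  )
  if (any(df$pos < 1)) stop("positions must be >= 1")
  if (!all(df$ref %in% DNA_BASES) || !all(df$alt %in% DNA_BASES))
    stop("alleles must be single bases A/C/G/T")
  if (any(df$ref == df$alt)) stop("ref and alt alleles must differ")
  if (!all(df$zygosity %in% c("HOM", "HET")))
    stop("zygosity must be HOM or HET")
  if (any(df$depth < 0)) stop("depth must be non-negative")
  df <- df[order(df$contig, df$pos), , drop = FALSE]
  df$key <- site_key(df$contig, df$pos)
  if (anyDuplicated(df$key))
    stop("duplicate site(s) in call set: ",
         paste(utils::head(df$key[duplicated(df$key)], 3), collapse = ", "))
  rownames(df) <- NULL
  df
}

#' Read biallelic SNVs from a single-sample VCF
#'
#' Keeps only single-nucleotide records. Multiallelic records are split per
#' alt allele; any alt that is not a single base is dropped. Zygosity comes
#' from the GT field (`0/1` -> HET, `1/1` -> HOM; `|`-phased genotypes are
#' accepted); depth from the per-sample DP field, else the INFO DP, else 0.
#'
#' @param path path to a VCF (v4.x) with exactly one sample.
#' @return a variant-call `data.frame` (see [variant_calls()]).
#' @export
read_snvs <- function(path) {
  if (!file.exists(path)) stop("cannot read VCF: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- v@gt
  n_samp <- ncol(gt) - 1L
  if (is.null(gt) || n_samp < 1L) stop("VCF has no sample genotype columns")
  if (n_samp != 1L)
    stop("expected a single-sample VCF, found ", n_samp, " samples")
  fix <- v@fix
  if (nrow(fix) == 0)
    return(variant_calls(character(), integer(), character(), character(),
                         character()))
  gts <- vcfR::extract.gt(v, element = "GT")[, 1]
  fmt <- colnames(gt)[1]
  dp <- rep(NA_character_, nrow(fix))
  if (any(grepl("\\bDP\\b", gt[, fmt])))
    dp <- suppressWarnings(vcfR::extract.gt(v, element = "DP")[, 1])
  dp_num <- suppressWarnings(as.integer(dp))
  if (all(is.na(dp_num)) && !is.null(fix[, "INFO"])) {
    m <- regmatches(fix[, "INFO"], regexpr("(?<=\\bDP=)[0-9]+",
                                           fix[, "INFO"], perl = TRUE))
    if (length(m) == nrow(fix)) dp_num <- suppressWarnings(as.integer(m))
  }
  dp_num[is.na(dp_num)] <- 0L

  out <- vector("list", nrow(fix))
  for (i in seq_len(nrow(fix))) {
    ref <- toupper(fix[i, "REF"])
    if (nchar(ref) != 1 || !ref %in% DNA_BASES) next
    alts <- toupper(strsplit(fix[i, "ALT"], ",", fixed = TRUE)[[1]])
    al <- strsplit(gts[i], "[/|]")[[1]]
    if (length(al) != 2 || anyNA(suppressWarnings(as.integer(al)))) next
    al <- as.integer(al)
    for (j in seq_along(alts)) {
      a <- alts[j]
      if (nchar(a) != 1 || !a %in% DNA_BASES || a == ref) next
      hits <- sum(al == j)
      if (hits == 0 || any(!al %in% c(0L, j))) next
      out[[i]] <- data.frame(
        contig = fix[i, "CHROM"], pos = as.integer(fix[i, "POS"]),
        ref = ref, alt = a,
        zygosity = if (hits == 2L) "HOM" else "HET",
        depth = dp_num[i], stringsAsFactors = FALSE
      )
      break # one genotype-supported alt per record after splitting
    }
  }
  out <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(out))
    return(variant_calls(character(), integer(), character(), character(),
                         character()))
  variant_calls(out$contig, out$pos, out$ref, out$alt, out$zygosity,
                out$depth)
}

#' Write a variant-call table as a minimal single-sample VCF
#'
#' @param calls a variant-call `data.frame`.
#' @param path output path.
#' @param sample sample name for the genotype column.
#' @param seqlengths optional named contig lengths for `##contig` headers.
#' @return the path, invisibly.
#' @export
write_snvs <- function(calls, path, sample = "SAMPLE", seqlengths = NULL) {
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=crossvar",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">'
  )
  if (!is.null(seqlengths))
    hdr <- c(hdr, sprintf("##contig=<ID=%s,length=%d>",
                          names(seqlengths), as.integer(seqlengths)))
  hdr <- c(hdr, paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", sample, sep = "\t"))
  gt <- ifelse(calls$zygosity == "HOM", "1/1", "0/1")
  body <- paste(calls$contig, calls$pos, ".", calls$ref, calls$alt, ".",
                "PASS", ".", "GT:DP", paste0(gt, ":", calls$depth),
                sep = "\t")
  writeLines(c(hdr, body), path, sep = "\n")
  invisible(path)
}

#' Read SNP-chip genotypes from a 4-column TSV
#'
#' Expected columns: contig, 1-based position, allele A, allele B (a header
#' line is detected and skipped). Such a table is produced from Affymetrix
#' birdseed calls by mapping each numeric genotype to its two probe alleles.
#' Zygosity is derived: HET iff the two alleles differ.
#'
#' @param path path to the TSV.
#' @return `data.frame` with columns contig, pos, allele_a, allele_b,
#'   zygosity, key.
#' @export
read_chip <- function(path) {
  if (!file.exists(path)) stop("cannot read chip table: ", path)
  lines <- readLines(path)
  first_data <- 1L
  if (length(lines)) {
    f1 <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
    if (length(f1) >= 2 && is.na(suppressWarnings(as.integer(f1[2]))))
      first_data <- 2L
  }
  lines <- lines[lines != ""]
  if (length(lines) < first_data)
    return(data.frame(contig = character(), pos = integer(),
                      allele_a = character(), allele_b = character(),
                      zygosity = character(), key = character(),
                      stringsAsFactors = FALSE))
  rows <- strsplit(lines[first_data:length(lines)], "\t", fixed = TRUE)
  bad_len <- which(lengths(rows) < 4)
  if (length(bad_len))
    stop("chip table line ", bad_len[1] + first_data - 1L,
         ": expected 4 tab-separated columns")
  m <- matrix(unlist(lapply(rows, `[`, 1:4)), ncol = 4, byrow = TRUE)
  a <- toupper(m[, 3]); b <- toupper(m[, 4])
  bad <- which(!(a %in% DNA_BASES & b %in% DNA_BASES))
  if (length(bad))
    stop("chip table line ", bad[1] + first_data - 1L,
         ": allele not in A/C/G/T")
  df <- data.frame(
    contig = m[, 1], pos = as.integer(m[, 2]),
    allele_a = a, allele_b = b,
    zygosity = ifelse(a == b, "HOM", "HET"),
    stringsAsFactors = FALSE
  )
  df$key <- site_key(df$contig, df$pos)
  if (anyDuplicated(df$key))
    stop("duplicate chip site(s): ",
         paste(utils::head(unique(df$key[duplicated(df$key)]), 3),
               collapse = ", "))
  df[order(df$contig, df$pos), , drop = FALSE]
}

#' Read a per-base track from a bedGraph-like TSV
#'
#' Rows are `contig<TAB>start<TAB>end<TAB>value` with 0-based half-open
#' intervals. Intervals are expanded to per-position values over the
#' declared contig spans; uncovered positions get 0. Overlapping rows are a
#' format error.
#'
#' @param path path to the TSV (empty file allowed).
#' @param seqlengths named integer vector declaring each contig's length.
#' @return a `per_base_track`: list with `values` (named list of numeric
#'   vectors, one element per position, 1-based) and `seqlengths`.
#' @export
read_track <- function(path, seqlengths) {
  if (is.null(names(seqlengths)) || any(names(seqlengths) == ""))
    stop("seqlengths must be a named vector of contig lengths")
  values <- lapply(seqlengths, function(L) numeric(L))
  info <- file.info(path)
  if (is.na(info$size)) stop("cannot read track: ", path)
  if (info$size > 0) {
    d <- utils::read.table(path, sep = "\t", header = FALSE,
                           col.names = c("contig", "start", "end", "value"),
                           colClasses = c("character", "integer", "integer",
                                          "numeric"))
    check_contigs(names(seqlengths), unique(c(names(seqlengths), d$contig)))
    for (ctg in unique(d$contig)) {
      rows <- d[d$contig == ctg, , drop = FALSE]
      rows <- rows[order(rows$start), , drop = FALSE]
      if (any(rows$end <= rows$start))
        stop("track interval with end <= start on ", ctg)
      if (any(rows$end > seqlengths[[ctg]]))
        stop("track interval beyond declared span of ", ctg)
      if (nrow(rows) > 1 &&
          any(rows$start[-1] < rows$end[-nrow(rows)]))
        stop("overlapping track intervals on ", ctg)
      idx <- sequence(rows$end - rows$start, from = rows$start + 1L)
      values[[ctg]][idx] <- rep(rows$value, rows$end - rows$start)
    }
  }
  structure(list(values = values, seqlengths = seqlengths),
            class = "per_base_track")
}

#' Write a per-base track as a bedGraph-like TSV
#'
#' Inverse of [read_track()]: maximal runs of equal non-zero values become
#' 0-based half-open rows.
#'
#' @param track a `per_base_track`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_track <- function(track, path) {
  con <- file(path, open = "w")
  on.exit(close(con))
  for (ctg in names(track$values)) {
    r <- rle(track$values[[ctg]])
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    keep <- r$values != 0
    if (any(keep))
      writeLines(paste(ctg, starts[keep], ends[keep],
                       format(r$values[keep], trim = TRUE, scientific = FALSE),
                       sep = "\t"), con)
  }
  invisible(path)
}

# per-position accessor: value of the track at (contig, 1-based pos)
track_at <- function(track, contig, pos) {
  mapply(function(c, p) track$values[[c]][p], contig, pos, USE.NAMES = FALSE)
}

#' Read/write region sets (BED)
#'
#' Regions are held as `GRanges` (1-based, closed) in memory and written as
#' standard 0-based half-open BED via rtracklayer; a write -> read -> write
#' cycle is byte-identical.
#'
#' @param regions a `GRanges`.
#' @param path file path.
#' @param labels optional name column (recycled).
#' @return `write_bed` the path invisibly; `read_bed` a `GRanges`.
#' @export
write_bed <- function(regions, path, labels = NULL) {
  regions <- normalize_regions(regions, merge = FALSE)
  if (is.null(labels) && !is.null(S4Vectors::mcols(regions)$name))
    labels <- S4Vectors::mcols(regions)$name
  ctg <- as.character(GenomicRanges::seqnames(regions))
  start0 <- GenomicRanges::start(regions) - 1L
  end <- GenomicRanges::end(regions)
  lines <- if (length(regions) == 0) character(0)
           else if (is.null(labels)) paste(ctg, start0, end, sep = "\t")
           else paste(ctg, start0, end, rep_len(labels, length(regions)),
                      sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_bed
#' @export
read_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  normalize_regions(gr, merge = FALSE)
}

#' Normalize a region set
#'
#' Sorts intervals; with `merge = TRUE` also unions overlapping/adjacent
#' intervals, giving the canonical non-overlapping form.
#'
#' @param regions a `GRanges`.
#' @param merge union overlapping intervals (drops metadata).
#' @return sorted `GRanges`.
#' @export
normalize_regions <- function(regions, merge = TRUE) {
  if (merge) GenomicRanges::reduce(GenomicRanges::sort(regions))
  else GenomicRanges::sort(regions)
}

#' Read a reference FASTA
#'
#' @param path FASTA path.
#' @return a `DNAStringSet` named by contig (first whitespace token of each
#'   header).
#' @export
read_reference <- function(path) {
  s <- Biostrings::readDNAStringSet(path)
  names(s) <- sub("\\s.*$", "", names(s))
  s
}

#' @rdname read_reference
#' @param reference a `DNAStringSet`.
#' @export
write_reference <- function(reference, path) {
  Biostrings::writeXStringSet(reference, path, width = 70L)
  invisible(path)
}

#' Read per-site pileup base counts
#'
#' TSV with header `contig pos A C G T`: observed count of each base over
#' the reads covering the site.
#'
#' @param path path to the TSV.
#' @return `data.frame` with columns contig, pos, A, C, G, T, key.
#' @export
read_pileup <- function(path) {
  d <- utils::read.table(path, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE)
  need <- c("contig", "pos", "A", "C", "G", "T")
  if (!all(need %in% names(d)))
    stop("pileup table must have columns: ", paste(need, collapse = ", "))
  if (any(as.matrix(d[, DNA_BASES]) < 0)) stop("negative pileup count")
  d$key <- site_key(d$contig, d$pos)
  d[, c(need, "key")]
}

#' @rdname read_pileup
#' @param pileup a pileup `data.frame`.
#' @export
write_pileup <- function(pileup, path) {
  utils::write.table(pileup[, c("contig", "pos", "A", "C", "G", "T")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
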