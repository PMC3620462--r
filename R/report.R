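# Assembly of the summary tables: per-category chip-concordance with
# zygosity strata and median depths, the chip-discordance pattern matrix,
# chip-concordance inside/outside callable regions with chi-square and
# odds-ratio comparisons, and deterministic TSV/text rendering.

# records rows of one category as a pseudo call set on one platform
platform_calls <- function(records, platform) {
  z <- records[[paste0("zygosity_", platform)]]
  sel <- z != "ABSENT"
  data.frame(key = records$key[sel], contig = records$contig[sel],
             pos = records$pos[sel], ref = records$ref[sel],
             alt = records[[paste0("alt_", platform)]][sel],
             zygosity = z[sel],
             depth = records[[paste0("depth_", platform)]][sel],
             category = records$category[sel],
             stringsAsFactors = FALSE)
}

#' Per-category chip-concordance table
#'
#' For each concordance category, chip status and zygosity stratum (Total /
#' HOM / HET by the reported platform's sequencing zygosity), the number of
#' calls, its percentage of the category's chip-assayed sites on that
#' platform, and the median depth. Sites not on the chip are excluded from
#' counts and denominators.
#'
#' @param records output of [classify_sites()].
#' @param chip a chip genotype `data.frame`.
#' @param reference optional `DNAStringSet` for reference-allele checking.
#' @return `data.frame` with columns category, chip_status, stratum and,
#'   per platform, n, pct and median_depth.
#' @export
build_table1 <- function(records, chip, reference = NULL) {
  calls <- lapply(c(p1 = "p1", p2 = "p2"),
                  function(p) platform_calls(records, p))
  status <- lapply(calls, chip_status, chip = chip, reference = reference)
  rows <- list()
  for (cat in CONCORDANCE_CATEGORIES) {
    for (cs in c("CHIP_CONCORDANT", "CHIP_DISCORDANT")) {
      for (stratum in c("Total", "HOM", "HET")) {
        row <- list(category = cat, chip_status = cs, stratum = stratum)
        for (p in c("p1", "p2")) {
          cl <- calls[[p]]; st <- status[[p]]
          in_cat <- cl$category == cat
          assayed <- in_cat & st$status != "NOT_ON_CHIP"
          sel <- in_cat & st$status == cs &
            (stratum == "Total" | cl$zygosity == stratum)
          row[[paste0("n_", p)]] <- sum(sel)
          row[[paste0("pct_", p)]] <-
            if (any(in_cat)) pct_of(sum(sel), sum(assayed)) else NA_real_
          row[[paste0("median_depth_", p)]] <- median_depth(cl$depth[sel])
        }
        rows[[length(rows) + 1L]] <- as.data.frame(row,
                                                   stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Pattern matrix of chip-discordant concordant SNVs
#'
#' Applies [pattern_matrix()] to the sites that are concordant between
#' platforms but discordant with the chip.
#'
#' @inheritParams build_table1
#' @return a [pattern_matrix()] result.
#' @export
build_table2 <- function(records, chip, reference = NULL) {
  conc <- records[records$category == "CONCORDANT", , drop = FALSE]
  cl <- platform_calls(conc, "p1") # p1 and p2 genotypes agree here
  st <- chip_status(cl, chip, reference)
  sel <- st$status == "CHIP_DISCORDANT" & !is.na(st$chip_zygosity)
  pattern_matrix(st$chip_zygosity[sel], cl$zygosity[sel])
}

#' Callability gain of merged over single-platform data
#'
#' Merged callable fraction minus the mean of the two platforms' callable
#' fractions, in percentage points. Returned exact; rounding is applied at
#' render time.
#'
#' @param frac1,frac2,frac_merged callable percentages in \[0, 100\].
#' @param genome_length optional; if given, the gain is also expressed as a
#'   number of bases.
#' @return list: `gain_points` and (optionally) `gain_bases`.
#' @export
callability_gain <- function(frac1, frac2, frac_merged,
                             genome_length = NULL) {
  v <- c(frac1, frac2, frac_merged)
  if (any(v < 0 | v > 100)) stop("fractions must be percentages in [0,100]")
  gain <- frac_merged - (frac1 + frac2) / 2
  out <- list(gain_points = gain)
  if (!is.null(genome_length))
    out$gain_bases <- gain / 100 * genome_length
  out
}

#' Pearson chi-square and odds ratio for a 2x2 table
#'
#' Rows are the two datasets, columns chip-concordant / chip-discordant
#' counts. Chi-square is Pearson's without continuity correction (1 df) and
#' is `NA` when any margin is zero; `OR = (a*d)/(b*c)`, `NA` with a warning
#' when `b*c == 0` (no Haldane correction).
#'
#' @param a,b,c,d the four cell counts (row-wise), or `a` may be a 2x2
#'   matrix.
#' @param correct apply Yates continuity correction (default off).
#' @return list: `chi2`, `p_value`, `odds_ratio`.
#' @export
chi_square_or <- function(a, b = NULL, c = NULL, d = NULL, correct = FALSE) {
  m <- if (is.matrix(a)) a else matrix(c(a, c, b, d), 2, 2)
  if (any(m < 0)) stop("counts must be non-negative")
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    chi2 <- NA_real_; p <- NA_real_
  } else {
    ct <- suppressWarnings(stats::chisq.test(m, correct = correct))
    chi2 <- unname(ct$statistic); p <- unname(ct$p.value)
  }
  or <- if (m[1, 2] * m[2, 1] == 0) {
    warning("zero cell; odds ratio undefined")
    NA_real_
  } else (m[1, 1] * m[2, 2]) / (m[1, 2] * m[2, 1])
  list(chi2 = chi2, p_value = p, odds_ratio = or)
}

#' Merge two platforms' call sets
#'
#' Union of sites; at sites called by both platforms the call from the
#' deeper platform is kept (ties favour platform 1) with the summed depth,
#' approximating genotyping on merged alignments.
#'
#' @param p1,p2 variant-call `data.frame`s.
#' @return a variant-call `data.frame`.
#' @export
merge_calls <- function(p1, p2) {
  i2 <- match(p1$key, p2$key)
  shared <- !is.na(i2)
  take2 <- shared & p2$depth[i2] > p1$depth
  merged1 <- p1
  merged1$zygosity[take2] <- p2$zygosity[i2][take2]
  merged1$alt[take2] <- p2$alt[i2][take2]
  merged1$depth[shared] <- p1$depth[shared] + p2$depth[i2][shared]
  only2 <- p2[!p2$key %in% p1$key, , drop = FALSE]
  out <- rbind(merged1, only2)
  variant_calls(out$contig, out$pos, out$ref, out$alt, out$zygosity,
                out$depth)
}

#' Chip-concordance inside and outside callable regions
#'
#' For each dataset (each platform and the merged data), splits its
#' chip-assayed call sites by the dataset's callability state and computes
#' the chip-concordance rate in callable and non-callable regions, then
#' compares merged vs each platform (callable regions) with
#' [chi_square_or()].
#'
#' @param calls named list of call sets (`p1`, `p2`, `merged`).
#' @param tracks named list of matching `callability_track`s.
#' @param chip chip genotypes.
#' @param reference optional `DNAStringSet`.
#' @return list: `table` (dataset, region, counts, rate) and `tests`
#'   (merged_vs_p1, merged_vs_p2).
#' @export
build_table3 <- function(calls, tracks, chip, reference = NULL) {
  stopifnot(all(c("p1", "p2", "merged") %in% names(calls)),
            all(names(calls) %in% names(tracks)))
  cells <- list()
  for (ds in c("p1", "p2", "merged")) {
    cl <- calls[[ds]]
    st <- chip_status(cl, chip, reference)
    state <- track_state_at(tracks[[ds]], cl$contig, cl$pos)
    callable <- state == "CALLABLE"
    for (region in c("callable", "non_callable")) {
      sel <- if (region == "callable") callable else !callable
      nc <- sum(sel & st$status == "CHIP_CONCORDANT")
      nd <- sum(sel & st$status == "CHIP_DISCORDANT")
      cells[[length(cells) + 1L]] <- data.frame(
        dataset = ds, region = region, n_concordant = nc,
        n_discordant = nd, rate = concordance_rate(nc, nd),
        stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, cells)
  callable_counts <- function(ds) {
    r <- tab[tab$dataset == ds & tab$region == "callable", ]
    c(r$n_concordant, r$n_discordant)
  }
  m <- callable_counts("merged")
  tests <- list(
    merged_vs_p1 = chi_square_or(matrix(c(m, callable_counts("p1")),
                                        2, 2, byrow = TRUE)),
    merged_vs_p2 = chi_square_or(matrix(c(m, callable_counts("p2")),
                                        2, 2, byrow = TRUE)))
  list(table = tab, tests = tests)
}

fmt_num <- function(x, digits = 2) {
  ifelse(is.na(x), "NA", sprintf(paste0("%.", digits, "f"),
                                 round_half_up(x, digits)))
}

#' Render the summary report to TSV files and a text summary
#'
#' Writes table1.tsv, table2.tsv, table3.tsv, callability.tsv and
#' report.txt with deterministic column order and 2-dp rates (empty cells
#' render "NA", never "0.00"). Same input gives byte-identical output.
#'
#' @param report a report list as assembled by [run_pipeline()]: elements
#'   `counts`, `table1`, `table2`, `table3`, `callability`, `confident`,
#'   `het_rates`, `repeat_overlap`.
#' @param out_dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
render_reports <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  f <- function(x) file.path(out_dir, x)
  t1 <- report$table1
  for (col in grep("^pct_", names(t1))) t1[[col]] <- fmt_num(t1[[col]])
  for (col in grep("^median_depth_", names(t1)))
    t1[[col]] <- ifelse(is.na(t1[[col]]), "NA",
                        format(t1[[col]], trim = TRUE))
  utils::write.table(t1, f("table1.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)

  pm <- report$table2
  t2 <- data.frame(
    chip_zygosity = rep(rownames(pm$counts), each = 2),
    seq_zygosity = rep(colnames(pm$counts), 2),
    count = as.integer(t(pm$counts)),
    percent = fmt_num(as.numeric(t(pm$percent))),
    stringsAsFactors = FALSE)
  utils::write.table(t2, f("table2.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)

  t3 <- report$table3$table
  t3$rate <- fmt_num(t3$rate)
  utils::write.table(t3, f("table3.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)

  cb <- report$callability$per_dataset
  cb_rows <- do.call(rbind, lapply(names(cb), function(ds) {
    x <- cb[[ds]]
    data.frame(dataset = ds,
               callable_pct = fmt_num(x$callable_pct),
               callable_or_poor_mq_pct = fmt_num(x$callable_or_poor_mq_pct),
               noncallable_AT_fraction =
                 fmt_num(x$noncallable_AT_fraction, 4),
               stringsAsFactors = FALSE)
  }))
  utils::write.table(cb_rows, f("callability.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  cn <- report$counts
  gain <- report$callability$gain
  tst <- report$table3$tests
  lines <- c(
    "cross-platform SNV comparison summary",
    "",
    sprintf("sites total\t%d", sum(cn)),
    sprintf("concordant\t%d", cn[["CONCORDANT"]]),
    sprintf("discordant\t%d", cn[["DISCORDANT"]]),
    sprintf("p1-specific\t%d", cn[["P1_SPECIFIC"]]),
    sprintf("p2-specific\t%d", cn[["P2_SPECIFIC"]]),
    "",
    sprintf("heterozygosity p1-specific\t%s",
            fmt_num(report$het_rates[["P1_SPECIFIC"]])),
    sprintf("heterozygosity p2-specific\t%s",
            fmt_num(report$het_rates[["P2_SPECIFIC"]])),
    sprintf("repeat overlap p1-specific\t%s",
            fmt_num(report$repeat_overlap[["P1_SPECIFIC"]])),
    sprintf("repeat overlap p2-specific\t%s",
            fmt_num(report$repeat_overlap[["P2_SPECIFIC"]])),
    "",
    sprintf("confident het (concordant, chip-discordant)\t%d/%d (%s%%)",
            report$confident$n_confident, report$confident$n_total,
            fmt_num(report$confident$percent_headline, 0)),
    "",
    sprintf("callable p1\t%s", fmt_num(cb$p1$callable_pct)),
    sprintf("callable p2\t%s", fmt_num(cb$p2$callable_pct)),
    sprintf("callable merged\t%s", fmt_num(cb$merged$callable_pct)),
    sprintf("callability gain (points)\t%s", fmt_num(gain$gain_points)),
    sprintf("callability gain (bases)\t%s",
            fmt_num(gain$gain_bases, 0)),
    "",
    sprintf("merged vs p1 (callable): chi2=%s p=%s OR=%s",
            fmt_num(tst$merged_vs_p1$chi2),
            format(tst$merged_vs_p1$p_value, digits = 4),
            fmt_num(tst$merged_vs_p1$odds_ratio)),
    sprintf("merged vs p2 (callable): chi2=%s p=%s OR=%s",
            fmt_num(tst$merged_vs_p2$chi2),
            format(tst$merged_vs_p2$p_value, digits = 4),
            fmt_num(tst$merged_vs_p2$odds_ratio))
  )
  writeLines(lines, f("report.txt"))
  invisible(f(c("table1.tsv", "table2.tsv", "table3.tsv",
                "callability.tsv", "report.txt")))
}
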