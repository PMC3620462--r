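# End-to-end pipeline: (optional) simulation -> file round-trip ->
# concordance classification -> chip comparison -> confident-het filter ->
# callability -> rendered reports. Every stage consumes files, so each
# subcommand of the front-end script can be rerun alone.

stage_log <- function(...) message("[crossvar] ", sprintf(...))

#' Run the full comparison pipeline
#'
#' With `paths = NULL`, simulates a bundle under `out_dir/sim` first; the
#' analysis then reads every input back from disk (exercising the format
#' round-trip and allowing any stage to be rerun on its own files).
#' Contig names must match exactly across all inputs.
#'
#' @param config a [sim_config()] (used only when simulating).
#' @param out_dir output directory for the report bundle.
#' @param paths optional named list of existing input files: `reference`,
#'   `repeats`, `p1_vcf`, `p2_vcf`, `p1_depth`, `p1_mq`, `p2_depth`,
#'   `p2_mq`, `p2_pileup`, `chip`.
#' @param thresholds a [callability_thresholds()].
#' @param het_min_depth,het_min_second_fraction confident-het criterion
#'   parameters (strict `>`).
#' @return invisibly, a list with every intermediate and the rendered file
#'   paths.
#' @export
run_pipeline <- function(config = sim_config(), out_dir,
                         paths = NULL,
                         thresholds = callability_thresholds(),
                         het_min_depth = 20L,
                         het_min_second_fraction = 0.30) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (is.null(paths)) {
    stage_log("simulate: writing bundle (seed %d)", config$seed)
    bundle <- simulate_bundle(config, file.path(out_dir, "sim"))
    paths <- as.list(bundle$files)
  }
  reference <- read_reference(paths$reference)
  lens <- stats::setNames(Biostrings::width(reference), names(reference))
  repeats <- read_bed(paths$repeats)
  p1 <- read_snvs(paths$p1_vcf)
  p2 <- read_snvs(paths$p2_vcf)
  chip <- read_chip(paths$chip)
  check_contigs(names(reference),
                unique(c(names(reference), p1$contig, p2$contig,
                         chip$contig,
                         as.character(GenomicRanges::seqnames(repeats)))))
  stage_log("inputs: %d p1 calls, %d p2 calls, %d chip sites",
            nrow(p1), nrow(p2), nrow(chip))

  records <- classify_sites(p1, p2)
  counts <- concordance_counts(records)
  stage_log("classify: %s",
            paste(names(counts), counts, sep = "=", collapse = " "))

  table1 <- build_table1(records, chip, reference)
  table2 <- build_table2(records, chip, reference)

  # confident-het filter on platform-2 pileups at concordant,
  # chip-discordant heterozygous sites
  pile2 <- read_pileup(paths$p2_pileup)
  conc <- records[records$category == "CONCORDANT", , drop = FALSE]
  st_conc <- chip_status(platform_calls(conc, "p2"), chip, reference)
  het_cd_keys <- conc$key[st_conc$status == "CHIP_DISCORDANT" &
                            conc$zygosity_p2 == "HET"]
  pu <- pile2[pile2$key %in% het_cd_keys, , drop = FALSE]
  confident <- confident_fraction(pu[, DNA_BASES, drop = FALSE],
                                  min_depth = het_min_depth,
                                  min_second_fraction =
                                    het_min_second_fraction)
  stage_log("het-confidence: %d/%d confident",
            confident$n_confident, confident$n_total)

  # cumulative depth curves (platform-2 depths) of heterozygous call groups
  groups <- list(
    concordant_chip_concordant =
      conc$depth_p2[st_conc$status == "CHIP_CONCORDANT" &
                      conc$zygosity_p2 == "HET"],
    concordant_chip_discordant =
      conc$depth_p2[st_conc$status == "CHIP_DISCORDANT" &
                      conc$zygosity_p2 == "HET"],
    discordant = records$depth_p2[records$category == "DISCORDANT" &
                                    records$zygosity_p2 == "HET"])
  groups <- groups[vapply(groups, length, integer(1)) > 0]
  depth_curves <- if (length(groups)) depth_cumulative_curve(groups)
                  else NULL

  d1 <- read_track(paths$p1_depth, lens)
  m1 <- read_track(paths$p1_mq, lens)
  d2 <- read_track(paths$p2_depth, lens)
  m2 <- read_track(paths$p2_mq, lens)
  tracks <- list(p1 = build_track(d1, m1, thresholds),
                 p2 = build_track(d2, m2, thresholds),
                 merged = merge_tracks(d1, m1, d2, m2, thresholds))
  per_dataset <- lapply(tracks, function(tr) {
    comp <- noncallable_base_composition(tr, reference)
    list(callable_pct = callability_fraction(tr),
         callable_or_poor_mq_pct =
           callability_fraction(tr, c("CALLABLE", "POOR_MQ")),
         noncallable_AT_fraction =
           unname(comp$fractions[["A"]] + comp$fractions[["T"]]),
         composition = comp)
  })
  gain <- callability_gain(per_dataset$p1$callable_pct,
                           per_dataset$p2$callable_pct,
                           per_dataset$merged$callable_pct,
                           genome_length = sum(lens))
  stage_log("callability: p1=%.2f%% p2=%.2f%% merged=%.2f%% gain=%.2f",
            per_dataset$p1$callable_pct, per_dataset$p2$callable_pct,
            per_dataset$merged$callable_pct, gain$gain_points)

  calls3 <- list(p1 = p1, p2 = p2, merged = merge_calls(p1, p2))
  table3 <- build_table3(calls3, tracks, chip, reference)

  het_rates <- vapply(CONCORDANCE_CATEGORIES, function(k)
    heterozygosity_rate(records, k,
                        platform = if (k == "DISCORDANT") "p2" else NULL),
    numeric(1))
  rep_ov <- vapply(CONCORDANCE_CATEGORIES, repeat_overlap,
                   numeric(1), records = records, repeats = repeats)

  report <- list(counts = counts, table1 = table1, table2 = table2,
                 table3 = table3,
                 callability = list(per_dataset = per_dataset, gain = gain),
                 confident = confident, het_rates = het_rates,
                 repeat_overlap = rep_ov, depth_curves = depth_curves)
  files <- render_reports(report, out_dir)

  manifest <- list(
    inputs = paths[!vapply(paths, is.null, logical(1))],
    parameters = list(
      min_depth = thresholds$min_depth, min_mq = thresholds$min_mq,
      het_min_depth = het_min_depth,
      het_min_second_fraction = het_min_second_fraction),
    outputs = as.list(files))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  stage_log("report written to %s", out_dir)
  invisible(c(report, list(records = records, tracks = tracks,
                           files = files, paths = paths)))
}
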