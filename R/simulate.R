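# Seeded two-platform sequencing simulator. Emulates the features the
# downstream comparison is sensitive to: a diploid genome with tandem-repeat
# regions, ~60% heterozygosity among true variant sites, platform-specific
# dropout (AT-biased for platform 1, uniform for platform 2),
# depth-dependent het->hom undercalling, platform-specific call suppression
# enriched in repeats, and chip genotypes with het->hom genotyping errors.
# Each output file draws from its own RNG stream derived from (seed, role),
# so adding an output never perturbs the others.

#' Simulation configuration
#'
#' Defaults describe the study conditions the package is tested under:
#' heterozygosity 0.60 among true variant sites, ~70% of platform-specific
#' calls in repeats, mean depths 20 and 35 for the two platforms, and a
#' chip het->hom genotyping error of 0.10.
#'
#' @param genome_length total bases across contigs (>= 1000).
#' @param n_contigs number of contigs.
#' @param repeat_fraction fraction of the genome in tandem-repeat intervals
#'   (must be <= 0.9).
#' @param n_variant_sites number of true variant sites
#'   (< genome_length / 10).
#' @param het_fraction probability a true variant site is heterozygous.
#' @param mean_depth named vector `c(p1 =, p2 =)` of mean sequencing depths.
#' @param dropout_model named vector, each `"at_biased"` or `"uniform"`.
#' @param dropout_rate named vector: fraction of the genome zeroed out per
#'   platform.
#' @param at_bias_strength exponent in the AT-biased dropout window weight
#'   `exp(strength * AT_fraction)`.
#' @param het_to_hom_base_rate,het_to_hom_depth_scale a true HET covered at
#'   depth d is miscalled HOM-alt with probability
#'   `base_rate * exp(-d / depth_scale)`.
#' @param platform_specific_rate fraction of truth sites made specific to
#'   each platform (absent from the other).
#' @param repeat_enrichment fraction of each platform-specific set placed in
#'   repeat regions.
#' @param chip_site_fraction fraction of truth sites assayed by the chip.
#' @param chip_het_to_hom_error probability the chip reports a true HET as
#'   HOM (one allele duplicated at random).
#' @param low_mq_repeat_fraction fraction of repeat bases given mapping
#'   quality below the callability threshold (shared between platforms:
#'   mappability is a genome property).
#' @param depth_window width (bases) of the piecewise-constant depth blocks.
#' @param min_call_depth sites below this depth are not called.
#' @param seed integer master seed.
#' @return a validated `sim_config` list.
#' @export
sim_config <- function(genome_length = 400000L, n_contigs = 2L,
                       repeat_fraction = 0.30, n_variant_sites = 5000L,
                       het_fraction = 0.60,
                       mean_depth = c(p1 = 20, p2 = 35),
                       dropout_model = c(p1 = "at_biased", p2 = "uniform"),
                       dropout_rate = c(p1 = 0.005, p2 = 0.005),
                       at_bias_strength = 10,
                       het_to_hom_base_rate = 0.6,
                       het_to_hom_depth_scale = 4,
                       platform_specific_rate = 0.10,
                       repeat_enrichment = 0.70,
                       chip_site_fraction = 0.50,
                       chip_het_to_hom_error = 0.10,
                       low_mq_repeat_fraction = 0.50,
                       depth_window = 25L, min_call_depth = 4L,
                       seed = 1L) {
  cfg <- list(genome_length = as.integer(genome_length),
              n_contigs = as.integer(n_contigs),
              repeat_fraction = repeat_fraction,
              n_variant_sites = as.integer(n_variant_sites),
              het_fraction = het_fraction, mean_depth = mean_depth,
              dropout_model = dropout_model, dropout_rate = dropout_rate,
              at_bias_strength = at_bias_strength,
              het_to_hom_base_rate = het_to_hom_base_rate,
              het_to_hom_depth_scale = het_to_hom_depth_scale,
              platform_specific_rate = platform_specific_rate,
              repeat_enrichment = repeat_enrichment,
              chip_site_fraction = chip_site_fraction,
              chip_het_to_hom_error = chip_het_to_hom_error,
              low_mq_repeat_fraction = low_mq_repeat_fraction,
              depth_window = as.integer(depth_window),
              min_call_depth = as.integer(min_call_depth),
              seed = as.integer(seed))
  props <- c(cfg$repeat_fraction, cfg$het_fraction, cfg$dropout_rate,
             cfg$het_to_hom_base_rate, cfg$platform_specific_rate,
             cfg$repeat_enrichment, cfg$chip_site_fraction,
             cfg$chip_het_to_hom_error, cfg$low_mq_repeat_fraction)
  if (any(props < 0 | props > 1))
    stop("all proportions must be in [0, 1]")
  if (cfg$repeat_fraction > 0.9)
    stop("repeat_fraction > 0.9 is infeasible")
  if (cfg$genome_length < 1000) stop("genome_length must be >= 1000")
  if (cfg$n_variant_sites >= cfg$genome_length / 10)
    stop("n_variant_sites must be < genome_length / 10")
  for (p in c("p1", "p2"))
    if (!p %in% names(cfg$mean_depth) || !p %in% names(cfg$dropout_model) ||
        !p %in% names(cfg$dropout_rate))
      stop("mean_depth, dropout_model and dropout_rate need entries p1, p2")
  if (!all(cfg$dropout_model %in% c("at_biased", "uniform")))
    stop("dropout_model entries must be 'at_biased' or 'uniform'")
  class(cfg) <- "sim_config"
  cfg
}

contig_lengths <- function(config) {
  base <- config$genome_length %/% config$n_contigs
  lens <- rep(base, config$n_contigs)
  lens[1] <- lens[1] + config$genome_length - sum(lens)
  stats::setNames(as.integer(lens), paste0("contig", seq_len(config$n_contigs)))
}

#' Simulate a reference genome with tandem-repeat regions
#'
#' Sequence is i.i.d. uniform A/C/G/T outside repeats; each repeat interval
#' is tandem copies of a short (2-8 bp) random motif. Repeat intervals are
#' spread across the genome and cover `repeat_fraction` of it to within 2%.
#'
#' @param config a [sim_config()].
#' @return list with `reference` (`DNAStringSet`) and `repeats` (`GRanges`).
#' @export
simulate_reference <- function(config) {
  lens <- contig_lengths(config)
  with_rng(role_seed(config$seed, "reference"), {
    seqs <- character(length(lens))
    rep_ctg <- character(0); rep_start <- integer(0); rep_end <- integer(0)
    for (i in seq_along(lens)) {
      L <- lens[[i]]
      chars <- sample(DNA_BASES, L, replace = TRUE)
      target <- round(config$repeat_fraction * L)
      if (target > 0) {
        n_rep <- max(1L, round(target / 500))
        sizes <- rep(target %/% n_rep, n_rep)
        extra <- target - sum(sizes)
        if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
        block <- L %/% n_rep
        if (max(sizes) >= block)
          stop("repeat intervals do not fit; lower repeat_fraction")
        for (j in seq_len(n_rep)) {
          off <- sample.int(block - sizes[j], 1L) - 1L
          s <- (j - 1L) * block + off + 1L   # 1-based start
          e <- s + sizes[j] - 1L
          mlen <- sample(2:8, 1L)
          motif <- sample(DNA_BASES, mlen, replace = TRUE)
          chars[s:e] <- rep_len(motif, sizes[j])
          rep_ctg <- c(rep_ctg, names(lens)[i])
          rep_start <- c(rep_start, s); rep_end <- c(rep_end, e)
        }
      }
      seqs[i] <- paste(chars, collapse = "")
    }
    reference <- Biostrings::DNAStringSet(stats::setNames(seqs, names(lens)))
    repeats <- GenomicRanges::GRanges(
      seqnames = factor(rep_ctg, levels = names(lens)),
      ranges = IRanges::IRanges(start = rep_start, end = rep_end),
      seqlengths = lens)
    list(reference = reference, repeats = normalize_regions(repeats))
  })
}

#' Simulate true diploid genotypes at variant sites
#'
#' Sites are drawn without replacement over the genome; each is HET with
#' probability `het_fraction`; the alt allele is uniform over the three
#' non-reference bases.
#'
#' @param config a [sim_config()].
#' @param genome output of [simulate_reference()].
#' @return truth `data.frame`: contig, pos, ref, alt, zygosity,
#'   repeat_flag, key.
#' @export
simulate_truth <- function(config, genome) {
  lens <- contig_lengths(config)
  n <- config$n_variant_sites
  with_rng(role_seed(config$seed, "truth"), {
    gidx <- sort(sample.int(sum(lens), n))
    cum <- cumsum(as.numeric(lens))
    ctg_i <- findInterval(gidx - 1, c(0, cum[-length(cum)]))
    pos <- as.integer(gidx - c(0, cum)[ctg_i])
    contig <- names(lens)[ctg_i]
    seq_chars <- lapply(as.character(genome$reference), identity)
    ref <- vapply(seq_len(n),
                  function(i) substr(seq_chars[[contig[i]]], pos[i], pos[i]),
                  character(1))
    zyg <- ifelse(stats::runif(n) < config$het_fraction, "HET", "HOM")
    alt_tbl <- t(vapply(DNA_BASES, function(b) setdiff(DNA_BASES, b),
                        character(3)))
    alt <- alt_tbl[cbind(match(ref, DNA_BASES), sample.int(3, n, TRUE))]
    gr <- GenomicRanges::GRanges(contig, IRanges::IRanges(pos, pos))
    rf <- IRanges::overlapsAny(gr, genome$repeats)
    df <- data.frame(contig = contig, pos = pos, ref = ref, alt = alt,
                     zygosity = zyg, repeat_flag = rf,
                     stringsAsFactors = FALSE)
    df <- df[order(df$contig, df$pos), , drop = FALSE]
    df$key <- site_key(df$contig, df$pos)
    rownames(df) <- NULL
    df
  })
}

# Piecewise-constant per-base depth for one platform: Poisson window depths,
# then dropout windows (AT-weighted or uniform) zeroed out. Deterministic
# given (config, platform_id).
platform_depth <- function(config, genome, platform_id) {
  lens <- contig_lengths(config)
  w <- config$depth_window
  with_rng(role_seed(config$seed, paste0(platform_id, "_depth")), {
    values <- vector("list", length(lens)); names(values) <- names(lens)
    win_at <- numeric(0); win_ctg <- character(0); win_start <- integer(0)
    for (ctg in names(lens)) {
      L <- lens[[ctg]]
      n_win <- ceiling(L / w)
      wd <- stats::rpois(n_win, config$mean_depth[[platform_id]])
      sizes <- c(rep(w, n_win - 1L), L - w * (n_win - 1L))
      values[[ctg]] <- rep(wd, times = sizes)
      starts <- seq.int(1L, by = w, length.out = n_win)
      at <- Biostrings::letterFrequency(
        Biostrings::Views(genome$reference[[ctg]],
                          start = starts, end = starts + sizes - 1L),
        "AT") / sizes
      win_at <- c(win_at, as.numeric(at))
      win_ctg <- c(win_ctg, rep(ctg, n_win))
      win_start <- c(win_start, starts)
    }
    n_drop <- round(config$dropout_rate[[platform_id]] * length(win_at))
    if (n_drop > 0) {
      wts <- if (config$dropout_model[[platform_id]] == "at_biased")
        exp(config$at_bias_strength * win_at) else rep(1, length(win_at))
      drop <- sample.int(length(win_at), n_drop, prob = wts)
      for (k in drop) {
        ctg <- win_ctg[k]
        s <- win_start[k]
        e <- min(s + w - 1L, lens[[ctg]])
        values[[ctg]][s:e] <- 0
      }
    }
    structure(list(values = values, seqlengths = lens),
              class = "per_base_track")
  })
}

# Low-mapping-quality region mask, shared between platforms (mappability is
# a property of the genome): a subset of repeat intervals trimmed to cover
# low_mq_repeat_fraction of all repeat bases.
low_mq_regions <- function(config, genome) {
  reps <- genome$repeats
  target <- round(config$low_mq_repeat_fraction *
                    sum(GenomicRanges::width(reps)))
  if (target == 0 || length(reps) == 0)
    return(GenomicRanges::GRanges())
  with_rng(role_seed(config$seed, "mq_mask"), {
    ord <- sample.int(length(reps))
    wid <- GenomicRanges::width(reps)[ord]
    k <- which(cumsum(wid) >= target)[1]
    if (is.na(k)) k <- length(ord)
    sel <- reps[ord[seq_len(k)]]
    over <- sum(GenomicRanges::width(sel)) - target
    if (over > 0) # trim the last picked interval to hit the target
      GenomicRanges::end(sel)[k] <- GenomicRanges::end(sel)[k] - over
    normalize_regions(sel)
  })
}

# Indices of truth sites a platform fails to cover at callable depth
# (dropout windows or Poisson depth below min_call_depth).
incidental_missing <- function(config, truth, depth_track) {
  d <- track_at(depth_track, truth$contig, truth$pos)
  which(d < config$min_call_depth)
}

#' Platform-specific suppression sets
#'
#' Decides, per platform, which truth sites are withheld from its call set
#' so that they end up specific to the other platform. The union of
#' incidentally missing sites (dropout / low depth) and deliberately
#' suppressed sites totals `platform_specific_rate` of the truth sites, with
#' `repeat_enrichment` of them inside repeat regions; the two platforms'
#' sets are disjoint so no site vanishes from both.
#'
#' @param config a [sim_config()].
#' @param truth output of [simulate_truth()].
#' @param genome output of [simulate_reference()].
#' @return list `p1`/`p2` of truth keys to suppress from that platform.
#' @export
suppression_sets <- function(config, truth, genome) {
  i1 <- incidental_missing(config, truth, platform_depth(config, genome, "p1"))
  i2 <- incidental_missing(config, truth, platform_depth(config, genome, "p2"))
  n <- nrow(truth)
  n_spec <- round(config$platform_specific_rate * n)
  take <- function(x, k) x[sample.int(length(x), min(k, length(x)))]
  pick <- function(role, incidental, excluded) {
    with_rng(role_seed(config$seed, role), {
      need <- max(0L, n_spec - length(incidental))
      rep_target <- round(config$repeat_enrichment * n_spec)
      rep_have <- sum(truth$repeat_flag[incidental])
      need_rep <- min(need, max(0L, rep_target - rep_have))
      need_non <- need - need_rep
      cand <- setdiff(seq_len(n), c(incidental, excluded))
      sort(c(take(cand[truth$repeat_flag[cand]], need_rep),
             take(cand[!truth$repeat_flag[cand]], need_non)))
    })
  }
  s1 <- pick("suppress_p1", i1, i2)
  s2 <- pick("suppress_p2", i2, c(i1, s1))
  list(p1 = truth$key[s1], p2 = truth$key[s2])
}

#' Simulate one platform's call set and depth/MQ tracks
#'
#' Per-base depth is Poisson in `depth_window` blocks, zeroed in
#' platform-specific dropout regions. A true HET covered at depth d is
#' miscalled HOM-alt with probability `base_rate * exp(-d / depth_scale)`;
#' sites below `min_call_depth` (and sites in this platform's suppression
#' set) are not called. Mapping quality is 60 outside the shared low-MQ
#' repeat mask, 5 inside it, and 0 wherever depth is 0. Pileup base counts
#' are generated for every called site (binomial allele sampling consistent
#' with the emitted genotype).
#'
#' @param config a [sim_config()].
#' @param truth output of [simulate_truth()].
#' @param genome output of [simulate_reference()].
#' @param platform_id `"p1"` or `"p2"`.
#' @param suppressed optional precomputed [suppression_sets()] result.
#' @return list with `calls` (variant-call `data.frame`), `depth` and `mq`
#'   (`per_base_track`s) and `pileup` (`data.frame`).
#' @export
simulate_platform <- function(config, truth, genome, platform_id,
                              suppressed = NULL) {
  stopifnot(nrow(truth) > 0, platform_id %in% c("p1", "p2"))
  depth <- platform_depth(config, genome, platform_id)
  if (is.null(suppressed))
    suppressed <- suppression_sets(config, truth, genome)

  lens <- depth$seqlengths
  lowmq <- low_mq_regions(config, genome)
  mq_vals <- lapply(names(lens), function(ctg) {
    v <- rep(60, lens[[ctg]])
    sel <- lowmq[as.logical(GenomicRanges::seqnames(lowmq) == ctg)]
    if (length(sel)) {
      idx <- sequence(GenomicRanges::width(sel),
                      from = GenomicRanges::start(sel))
      v[idx] <- 5
    }
    v[depth$values[[ctg]] == 0] <- 0
    v
  })
  names(mq_vals) <- names(lens)
  mq <- structure(list(values = mq_vals, seqlengths = lens),
                  class = "per_base_track")

  d_site <- track_at(depth, truth$contig, truth$pos)
  n <- nrow(truth)
  zyg <- with_rng(role_seed(config$seed, paste0(platform_id, "_calls")), {
    u <- stats::runif(n)
    err_p <- config$het_to_hom_base_rate *
      exp(-d_site / config$het_to_hom_depth_scale)
    ifelse(truth$zygosity == "HET" & u < err_p, "HOM", truth$zygosity)
  })
  keep <- d_site >= config$min_call_depth &
    !truth$key %in% suppressed[[platform_id]]
  calls <- variant_calls(truth$contig[keep], truth$pos[keep],
                         truth$ref[keep], truth$alt[keep],
                         zyg[keep], as.integer(d_site[keep]))

  pileup <- with_rng(role_seed(config$seed, paste0(platform_id, "_pileup")), {
    d <- calls$depth
    # ref-allele sampling probability given the emitted genotype
    p_ref <- ifelse(calls$zygosity == "HET", 0.5,
                    ifelse(truth$zygosity[match(calls$key, truth$key)] ==
                             "HET", 0.05, 0.02))
    ref_n <- stats::rbinom(length(d), d, p_ref)
    m <- matrix(0L, nrow = length(d), ncol = 4,
                dimnames = list(NULL, DNA_BASES))
    m[cbind(seq_along(d), match(calls$ref, DNA_BASES))] <- ref_n
    m[cbind(seq_along(d), match(calls$alt, DNA_BASES))] <- d - ref_n
    cbind(calls[, c("contig", "pos")], as.data.frame(m))
  })
  pileup$key <- site_key(pileup$contig, pileup$pos)

  list(calls = calls, depth = depth, mq = mq, pileup = pileup)
}

#' Simulate SNP-chip genotypes
#'
#' Assays `chip_site_fraction` of the truth sites; a true HET is reported
#' HOM (one of its two alleles duplicated, chosen at random) with
#' probability `chip_het_to_hom_error`. Allele pairs are emitted in
#' alphabetical order.
#'
#' @param config a [sim_config()].
#' @param truth output of [simulate_truth()].
#' @return chip `data.frame`: contig, pos, allele_a, allele_b, zygosity,
#'   key.
#' @export
simulate_chip <- function(config, truth) {
  stopifnot(nrow(truth) > 0)
  with_rng(role_seed(config$seed, "chip"), {
    n <- nrow(truth)
    k <- round(config$chip_site_fraction * n)
    idx <- sort(sample.int(n, k))
    t <- truth[idx, , drop = FALSE]
    a <- ifelse(t$zygosity == "HET", t$ref, t$alt)
    b <- t$alt
    err <- t$zygosity == "HET" &
      stats::runif(k) < config$chip_het_to_hom_error
    dup_first <- stats::runif(k) < 0.5
    a[err] <- ifelse(dup_first[err], t$ref[err], t$alt[err])
    b[err] <- a[err]
    lo <- pmin(a, b); hi <- pmax(a, b)
    data.frame(contig = t$contig, pos = t$pos, allele_a = lo, allele_b = hi,
               zygosity = ifelse(lo == hi, "HOM", "HET"), key = t$key,
               stringsAsFactors = FALSE, row.names = NULL)
  })
}

#' Simulate the full two-platform bundle in memory
#'
#' @param config a [sim_config()].
#' @return list: `config`, `genome` (reference + repeats), `truth`, `p1`,
#'   `p2` (each a [simulate_platform()] result) and `chip`.
#' @export
simulate_all <- function(config = sim_config()) {
  genome <- simulate_reference(config)
  truth <- simulate_truth(config, genome)
  sup <- suppression_sets(config, truth, genome)
  list(config = config, genome = genome, truth = truth,
       p1 = simulate_platform(config, truth, genome, "p1", sup),
       p2 = simulate_platform(config, truth, genome, "p2", sup),
       chip = simulate_chip(config, truth))
}

#' Simulate and write the full bundle to a directory
#'
#' Writes reference.fa, repeats.bed, truth.tsv, p1.vcf, p2.vcf,
#' p{1,2}.depth.bedgraph, p{1,2}.mq.bedgraph, p{1,2}.pileup.tsv, chip.tsv
#' and sim_params.tsv. Byte-identical across runs with the same config.
#'
#' @param config a [sim_config()].
#' @param out_dir output directory (created if needed).
#' @return invisibly, the [simulate_all()] bundle with `$files` added.
#' @export
simulate_bundle <- function(config = sim_config(), out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  b <- simulate_all(config)
  lens <- contig_lengths(config)
  f <- function(x) file.path(out_dir, x)
  write_reference(b$genome$reference, f("reference.fa"))
  write_bed(b$genome$repeats, f("repeats.bed"), labels = "repeat")
  utils::write.table(b$truth[, c("contig", "pos", "ref", "alt", "zygosity",
                                 "repeat_flag")],
                     f("truth.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  for (p in c("p1", "p2")) {
    write_snvs(b[[p]]$calls, f(paste0(p, ".vcf")), sample = p,
               seqlengths = lens)
    write_track(b[[p]]$depth, f(paste0(p, ".depth.bedgraph")))
    write_track(b[[p]]$mq, f(paste0(p, ".mq.bedgraph")))
    write_pileup(b[[p]]$pileup, f(paste0(p, ".pileup.tsv")))
  }
  utils::write.table(b$chip[, c("contig", "pos", "allele_a", "allele_b")],
                     f("chip.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  flat <- unlist(config[setdiff(names(config), character(0))])
  utils::write.table(data.frame(key = names(flat), value = as.character(flat)),
                     f("sim_params.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  b$files <- stats::setNames(
    f(c("reference.fa", "repeats.bed", "truth.tsv", "p1.vcf", "p2.vcf",
        "p1.depth.bedgraph", "p1.mq.bedgraph", "p2.depth.bedgraph",
        "p2.mq.bedgraph", "p1.pileup.tsv", "p2.pileup.tsv", "chip.tsv",
        "sim_params.tsv")),
    c("reference", "repeats", "truth", "p1_vcf", "p2_vcf", "p1_depth",
      "p1_mq", "p2_depth", "p2_mq", "p1_pileup", "p2_pileup", "chip",
      "params"))
  invisible(b)
}
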