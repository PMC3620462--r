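# Fixture builders and independent brute-force oracles used across tests.

# write a minimal single-sample VCF from body lines
write_test_vcf <- function(body, path = tempfile(fileext = ".vcf"),
                           samples = "S1") {
  hdr <- c("##fileformat=VCFv4.2",
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
           '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Depth">',
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", samples), collapse = "\t"))
  writeLines(c(hdr, body), path)
  path
}

# deterministic reference base for a synthetic site universe
ref_at <- function(pos) c("A", "C", "G", "T")[(pos %% 4) + 1]

# random call set over positions 1..span on one contig; ref is a fixed
# function of position so two sets never disagree on ref
random_call_set <- function(n, span = 500, contig = "c1") {
  pos <- sort(sample.int(span, n))
  ref <- ref_at(pos)
  alt <- vapply(ref, function(r) sample(setdiff(c("A", "C", "G", "T"), r), 1),
                character(1))
  variant_calls(contig, pos, ref, alt,
                sample(c("HOM", "HET"), n, replace = TRUE),
                sample.int(60, n, replace = TRUE))
}

# brute-force per-site dictionary comparison (independent of classify_sites)
oracle_classify_counts <- function(p1, p2) {
  d1 <- split(seq_len(nrow(p1)), p1$key)
  d2 <- split(seq_len(nrow(p2)), p2$key)
  keys <- union(p1$key, p2$key)
  out <- c(CONCORDANT = 0L, DISCORDANT = 0L, P1_SPECIFIC = 0L,
           P2_SPECIFIC = 0L)
  for (k in keys) {
    i <- d1[[k]]; j <- d2[[k]]
    cat <- if (is.null(j)) "P1_SPECIFIC"
           else if (is.null(i)) "P2_SPECIFIC"
           else if (p1$alt[i] == p2$alt[j] &&
                    p1$zygosity[i] == p2$zygosity[j]) "CONCORDANT"
           else "DISCORDANT"
    out[cat] <- out[cat] + 1L
  }
  out
}

# independent re-implementation of the confident-het comparisons
oracle_confident_count <- function(mat, min_depth = 20,
                                   min_second_fraction = 0.30) {
  n <- 0L
  for (i in seq_len(nrow(mat))) {
    cnt <- as.numeric(mat[i, ])
    tot <- sum(cnt)
    if (tot == 0) next
    second <- sort(cnt, decreasing = TRUE)[2]
    if (tot > min_depth && second / tot > min_second_fraction) n <- n + 1L
  }
  n
}

# brute-force Pearson chi-square from expected counts
oracle_chi2 <- function(m) {
  e <- outer(rowSums(m), colSums(m)) / sum(m)
  sum((m - e)^2 / e)
}

# small, fast simulation config for smoke/property tests
tiny_config <- function(...) {
  args <- list(genome_length = 60000L, n_contigs = 2L,
               n_variant_sites = 800L, chip_site_fraction = 0.6)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(sim_config, args)
}

# directory fingerprint for byte-identity checks
dir_digest <- function(dir) {
  files <- sort(list.files(dir, recursive = TRUE, full.names = TRUE))
  vapply(files, function(f) paste(tools::md5sum(f)), character(1))
}
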