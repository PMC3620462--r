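# Chip-concordance: genotype comparison, rates, pattern matrix, medians.

make_chip <- function(pos, a, b, contig = "c1") {
  data.frame(contig = contig, pos = pos, allele_a = a, allele_b = b,
             zygosity = ifelse(a == b, "HOM", "HET"),
             key = paste0(contig, ":", pos), stringsAsFactors = FALSE)
}

test_that("chip_status compares unordered genotypes with the reference", {
  calls <- variant_calls("c1", c(10, 20, 30, 40, 50),
                         rep("A", 5), rep("G", 5),
                         c("HET", "HOM", "HET", "HET", "HOM"), 10)
  chip <- make_chip(c(10, 20, 30, 40), c("A", "A", "G", "A"),
                    c("G", "G", "G", "A"))
  ref <- Biostrings::DNAStringSet(c(c1 = paste(rep("A", 60), collapse = "")))
  st <- chip_status(calls, chip, ref)
  expect_equal(st$status,
               c("CHIP_CONCORDANT",   # HET A>G vs {A,G}
                 "CHIP_DISCORDANT",   # HOM A>G implies {G,G} != {A,G}
                 "CHIP_DISCORDANT",   # HET A>G vs {G,G}
                 "CHIP_DISCORDANT",   # chip hom-ref {A,A} denies the variant
                 "NOT_ON_CHIP"))
  expect_equal(st$chip_zygosity[3], "HOM")
  expect_true(st$chip_hom_ref[4])
  expect_false(any(st$chip_hom_ref[-4]))
})

test_that("chip_status rejects calls whose ref disagrees with the genome", {
  calls <- variant_calls("c1", 10, "C", "G", "HET", 10)
  ref <- Biostrings::DNAStringSet(c(c1 = paste(rep("A", 20), collapse = "")))
  expect_error(chip_status(calls, make_chip(10, "C", "G"), ref),
               "reference mismatch")
})

test_that("status partition covers every call", {
  set.seed(4)
  calls <- random_call_set(80)
  on_chip <- sample.int(80, 50)
  chip <- make_chip(calls$pos[on_chip], calls$ref[on_chip],
                    calls$alt[on_chip])
  st <- chip_status(calls, chip)
  expect_equal(sum(st$status == "NOT_ON_CHIP"), 30)
  expect_equal(nrow(st), 80)
})

test_that("concordance_rate rounds half away from zero at 2 dp", {
  expect_equal(concordance_rate(5, 0), 100.00)
  expect_true(is.na(concordance_rate(0, 0)))
  # permutation invariance is trivial for counts; check a tie-rounding case
  expect_equal(concordance_rate(1, 7999), 0.01) # 0.0125% rounds to 0.01
  expect_equal(concordance_rate(1, 399), 0.25)
})

test_that("pattern_matrix tallies cells and percentages of the total", {
  pm <- pattern_matrix("HET", "HOM")
  expect_equal(pm$counts["HET", "HOM"], 1L)
  expect_equal(pm$percent["HET", "HOM"], 100.00)
  expect_equal(sum(pm$counts), pm$total)

  set.seed(5)
  cz <- sample(c("HOM", "HET"), 200, replace = TRUE)
  sz <- sample(c("HOM", "HET"), 200, replace = TRUE)
  pm <- pattern_matrix(cz, sz)
  expect_equal(sum(pm$counts), 200L)
  expect_true(abs(sum(pm$percent) - 100) < 0.05) # rounding slack
})

test_that("chip het-to-hom error concentrates in the (chip HOM, seq HET) cell", {
  cfg <- tiny_config(het_to_hom_base_rate = 0, seed = 19)
  b <- simulate_all(cfg)
  rec <- classify_sites(b$p1$calls, b$p2$calls)
  pm <- build_table2(rec, b$chip, b$genome$reference)
  expect_gt(pm$counts["HOM", "HET"], 0)
  expect_equal(sum(pm$counts) - pm$counts["HOM", "HET"], 0L)
})

test_that("median_depth uses the mean-of-middle-two convention", {
  expect_equal(median_depth(c(10, 11)), 10.5)
  expect_equal(median_depth(c(1, 2, 3)), 2)
  expect_equal(median_depth(c(4, 1, 3, 2)), 2.5)
  expect_true(is.na(median_depth(integer(0))))
})
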