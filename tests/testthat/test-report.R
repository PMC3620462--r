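# Summary tables, callability gain, chi-square/odds-ratio and rendering.

test_that("table 1 strata are internally consistent on simulated data", {
  cfg <- tiny_config(seed = 25)
  b <- simulate_all(cfg)
  rec <- classify_sites(b$p1$calls, b$p2$calls)
  t1 <- build_table1(rec, b$chip, b$genome$reference)
  for (cat in unique(t1$category)) {
    for (cs in unique(t1$chip_status)) {
      sub <- t1[t1$category == cat & t1$chip_status == cs, ]
      for (p in c("n_p1", "n_p2"))
        expect_equal(sub[[p]][sub$stratum == "Total"],
                     sum(sub[[p]][sub$stratum != "Total"]))
    }
  }
  # chip-concordant + chip-discordant totals account for every assayed call
  conc <- t1[t1$category == "CONCORDANT" & t1$stratum == "Total", ]
  assayed <- sum(conc$n_p1)
  cl <- rec[rec$category == "CONCORDANT", ]
  expect_equal(assayed, sum(cl$key %in% b$chip$key))
})

test_that("error-free bundles have empty discordant and chip-discordant cells", {
  cfg <- tiny_config(het_to_hom_base_rate = 0, chip_het_to_hom_error = 0,
                     dropout_rate = c(p1 = 0, p2 = 0),
                     platform_specific_rate = 0, seed = 27)
  b <- simulate_all(cfg)
  rec <- classify_sites(b$p1$calls, b$p2$calls)
  expect_equal(unname(concordance_counts(rec)[c("DISCORDANT")]), 0L)
  t1 <- build_table1(rec, b$chip, b$genome$reference)
  expect_true(all(t1$n_p1[t1$chip_status == "CHIP_DISCORDANT"] == 0))
})

test_that("callability_gain is exact arithmetic with base conversion", {
  g <- callability_gain(50, 50, 50)
  expect_equal(g$gain_points, 0)
  g <- callability_gain(98.30, 98.15, 99.66, genome_length = 2.85e9)
  expect_equal(g$gain_points, 1.435, tolerance = 1e-9)
  expect_equal(g$gain_bases / 1e6, 40.9, tolerance = 0.01)
  expect_error(callability_gain(-1, 50, 50), "percentages")
})

test_that("chi_square_or matches the expected-counts formula and OR arithmetic", {
  r <- chi_square_or(10, 10, 5, 20)
  expect_equal(r$odds_ratio, 4.0)
  m <- matrix(c(10, 5, 10, 20), 2, 2)
  expect_equal(r$chi2, oracle_chi2(m), tolerance = 1e-12)

  eq <- chi_square_or(30, 10, 60, 20) # equal row proportions
  expect_equal(eq$chi2, 0, tolerance = 1e-12)
  expect_equal(eq$odds_ratio, 1.0)

  expect_warning(z <- chi_square_or(5, 0, 3, 2), "odds ratio")
  expect_true(is.na(z$odds_ratio))
})

test_that("merge_calls keeps the deeper genotype and sums depth", {
  p1 <- variant_calls("c1", c(10, 20), c("A", "C"), c("G", "T"),
                      c("HET", "HOM"), c(5, 30))
  p2 <- variant_calls("c1", c(10, 30), c("A", "G"), c("G", "A"),
                      c("HOM", "HET"), c(20, 8))
  m <- merge_calls(p1, p2)
  expect_equal(nrow(m), 3)
  expect_equal(m$zygosity[m$pos == 10], "HOM") # p2 deeper
  expect_equal(m$depth[m$pos == 10], 25L)
  expect_equal(m$zygosity[m$pos == 30], "HET")
})

test_that("rendered reports are deterministic and self-consistent", {
  cfg <- tiny_config(seed = 29)
  d1 <- file.path(tempdir(), "rep_a"); d2 <- file.path(tempdir(), "rep_b")
  suppressMessages(run_pipeline(cfg, d1))
  suppressMessages(run_pipeline(cfg, d2))
  for (f in c("table1.tsv", "table2.tsv", "table3.tsv", "callability.tsv",
              "report.txt"))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)),
                     label = f)
  # every printed rate re-derives from the printed counts beside it
  t3 <- utils::read.table(file.path(d1, "table3.tsv"), header = TRUE,
                          sep = "\t", stringsAsFactors = FALSE)
  for (i in seq_len(nrow(t3))) {
    expected <- concordance_rate(t3$n_concordant[i], t3$n_discordant[i])
    got <- suppressWarnings(as.numeric(t3$rate[i]))
    if (is.na(expected)) expect_true(is.na(got) || t3$rate[i] == "NA")
    else expect_equal(got, expected)
  }
  t2 <- utils::read.table(file.path(d1, "table2.tsv"), header = TRUE,
                          sep = "\t", stringsAsFactors = FALSE)
  tot <- sum(t2$count)
  expect_equal(suppressWarnings(as.numeric(t2$percent)),
               unname(round_half_up(100 * t2$count / tot)))
  # empty cells render NA, never 0.00
  t1 <- utils::read.table(file.path(d1, "table1.tsv"), header = TRUE,
                          sep = "\t", stringsAsFactors = FALSE)
  empty_rows <- t1[t1$category == "P2_SPECIFIC", ]
  expect_true(all(is.na(empty_rows$pct_p1) | empty_rows$pct_p1 == "NA"))
  expect_true(all(is.na(empty_rows$median_depth_p1) |
                    empty_rows$median_depth_p1 == "NA"))
})
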