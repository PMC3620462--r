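# Per-base callability classification, merging and region export.

ptrack <- function(..., len = NULL) {
  v <- list(...)
  if (is.null(len)) len <- vapply(v, length, integer(1))
  structure(list(values = lapply(v, as.numeric),
                 seqlengths = stats::setNames(as.integer(len), names(v))),
            class = "per_base_track")
}

test_that("classify_base applies thresholds in coverage-first order", {
  t <- callability_thresholds()
  expect_equal(classify_base(0, 60, t), "NO_COVERAGE")
  expect_equal(classify_base(3, 60, t), "LOW_COVERAGE")
  expect_equal(classify_base(10, 5, t), "POOR_MQ")
  expect_equal(classify_base(4, 10, t), "CALLABLE") # boundaries inclusive
  expect_equal(classify_base(2, 0, t), "LOW_COVERAGE") # coverage precedes MQ
  expect_error(classify_base(-1, 60, t), "negative")
  expect_error(callability_thresholds(min_depth = 0), "min_depth")
})

test_that("build_track run-length encodes the per-base states", {
  d <- ptrack(c1 = c(5, 5, 0, 0, 5))
  m <- ptrack(c1 = c(60, 60, 0, 0, 60))
  tr <- build_track(d, m)
  expect_equal(tr$runs$c1$values, c("CALLABLE", "NO_COVERAGE", "CALLABLE"))
  expect_equal(tr$runs$c1$lengths, c(2L, 2L, 1L))
  expect_equal(decode_track(tr, "c1"),
               c("CALLABLE", "CALLABLE", "NO_COVERAGE", "NO_COVERAGE",
                 "CALLABLE"))
  expect_error(build_track(d, ptrack(c1 = rep(60, 9))), "different spans")
})

test_that("state fractions are conserved and computed exactly", {
  d <- ptrack(c1 = c(rep(10, 9930), rep(0, 70)))
  m <- ptrack(c1 = rep(60, 10000))
  tr <- build_track(d, m)
  expect_equal(callability_fraction(tr), 99.30)
  fr <- vapply(c("CALLABLE", "POOR_MQ", "LOW_COVERAGE", "NO_COVERAGE"),
               function(s) callability_fraction(tr, s), numeric(1))
  expect_equal(sum(fr), 100)
})

test_that("merging sums depth and weights MQ by depth", {
  t <- callability_thresholds()
  d1 <- ptrack(c1 = c(2, 0, 0)); m1 <- ptrack(c1 = c(60, 0, 0))
  d2 <- ptrack(c1 = c(3, 6, 0)); m2 <- ptrack(c1 = c(60, 30, 0))
  tr <- merge_tracks(d1, m1, d2, m2, t)
  # 2+3 reaches the depth threshold although both alone are LOW_COVERAGE
  expect_equal(decode_track(tr, "c1"),
               c("CALLABLE", "CALLABLE", "NO_COVERAGE"))
  # a platform with zero depth contributes nothing to merged MQ
  alone <- build_track(d2, m2, t)
  expect_equal(decode_track(tr, "c1")[2], decode_track(alone, "c1")[2])
})

test_that("export_regions round-trips through BED and preserves base counts", {
  set.seed(10)
  d <- ptrack(c1 = sample(0:6, 400, replace = TRUE))
  m <- ptrack(c1 = sample(c(5, 60), 400, replace = TRUE))
  tr <- build_track(d, m)
  counts <- vapply(c("CALLABLE", "POOR_MQ", "LOW_COVERAGE", "NO_COVERAGE"),
                   function(s) {
                     gr <- export_regions(tr, s)
                     p <- tempfile(fileext = ".bed")
                     write_bed(gr, p, labels = s)
                     back <- if (file.size(p) > 0) read_bed(p)
                             else GenomicRanges::GRanges()
                     expect_equal(sum(GenomicRanges::width(back)),
                                  sum(GenomicRanges::width(gr)))
                     sum(GenomicRanges::width(gr))
                   }, numeric(1))
  expect_equal(sum(counts), 400)
  st <- decode_track(tr, "c1")
  expect_equal(unname(counts["CALLABLE"]), sum(st == "CALLABLE"))
})

test_that("non-callable base composition reflects the reference", {
  ref <- Biostrings::DNAStringSet(c(c1 = paste(rep("A", 100), collapse = "")))
  d <- ptrack(c1 = c(rep(0, 40), rep(10, 60)))
  m <- ptrack(c1 = c(rep(0, 40), rep(60, 60)))
  comp <- noncallable_base_composition(build_track(d, m), ref)
  expect_equal(unname(comp$fractions[["A"]]), 1)
  expect_equal(comp$n_bases, 40)

  all_call <- build_track(ptrack(c1 = rep(10, 100)),
                          ptrack(c1 = rep(60, 100)))
  expect_true(all(is.na(
    noncallable_base_composition(all_call, ref)$fractions)))
})
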