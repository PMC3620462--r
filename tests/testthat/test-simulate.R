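# Simulator: configuration invariants, determinism, and the error models.

test_that("sim_config validates proportions and feasibility", {
  expect_error(sim_config(repeat_fraction = 0.95), "infeasible")
  expect_error(sim_config(het_fraction = 1.2), "proportions")
  expect_error(sim_config(genome_length = 500), "1000")
  expect_error(sim_config(genome_length = 2000, n_variant_sites = 500),
               "n_variant_sites")
})

test_that("simulated repeats cover the requested fraction of the genome", {
  cfg <- tiny_config(seed = 5)
  g <- simulate_reference(cfg)
  frac <- sum(GenomicRanges::width(g$repeats)) / cfg$genome_length
  expect_true(abs(frac - cfg$repeat_fraction) <= 0.02)

  g0 <- simulate_reference(tiny_config(repeat_fraction = 0, seed = 5))
  expect_equal(length(g0$repeats), 0)
})

test_that("same seed gives a byte-identical output bundle", {
  cfg <- tiny_config(seed = 42)
  d1 <- file.path(tempdir(), "bundle_a")
  d2 <- file.path(tempdir(), "bundle_b")
  simulate_bundle(cfg, d1)
  simulate_bundle(cfg, d2)
  expect_equal(unname(dir_digest(d1)), unname(dir_digest(d2)))
})

test_that("truth genotypes follow the heterozygosity model", {
  cfg <- tiny_config(seed = 9)
  g <- simulate_reference(cfg)
  truth <- simulate_truth(cfg, g)
  # binomial 99% interval at n = 800, p = 0.6 is about +/- 0.045
  expect_true(abs(mean(truth$zygosity == "HET") - 0.6) < 0.045)
  expect_true(all(truth$ref != truth$alt))

  all_het <- simulate_truth(tiny_config(het_fraction = 1, seed = 9), g)
  expect_true(all(all_het$zygosity == "HET"))
})

test_that("no-error platforms reproduce the truth at covered sites", {
  cfg <- tiny_config(het_to_hom_base_rate = 0,
                     dropout_rate = c(p1 = 0, p2 = 0),
                     platform_specific_rate = 0, seed = 3)
  g <- simulate_reference(cfg)
  truth <- simulate_truth(cfg, g)
  p1 <- simulate_platform(cfg, truth, g, "p1")
  covered <- truth[truth$key %in% p1$calls$key, ]
  expect_equal(p1$calls$zygosity, covered$zygosity)
  expect_equal(p1$calls$alt, covered$alt)
  # full Poisson coverage at mean 20: essentially every site called
  expect_gt(nrow(p1$calls) / nrow(truth), 0.999)
})

test_that("depth-independent het undercalling hits its configured rate", {
  cfg <- sim_config(genome_length = 120000L, n_variant_sites = 4000L,
                    het_fraction = 1, het_to_hom_base_rate = 0.5,
                    het_to_hom_depth_scale = 1e9,
                    dropout_rate = c(p1 = 0, p2 = 0),
                    platform_specific_rate = 0, seed = 13)
  g <- simulate_reference(cfg)
  truth <- simulate_truth(cfg, g)
  p1 <- simulate_platform(cfg, truth, g, "p1")
  frac_hom <- mean(p1$calls$zygosity == "HOM")
  # binomial 99% interval at n = 4000, p = 0.5: +/- 0.021
  expect_true(abs(frac_hom - 0.5) < 0.021)
})

test_that("chip genotyping follows the het-to-hom error model", {
  cfg <- sim_config(genome_length = 200000L, n_variant_sites = 5000L,
                    het_fraction = 1, chip_site_fraction = 1,
                    chip_het_to_hom_error = 0.1, seed = 17)
  g <- simulate_reference(cfg)
  truth <- simulate_truth(cfg, g)
  chip <- simulate_chip(cfg, truth)
  expect_equal(nrow(chip), 5000)
  frac_hom <- mean(chip$zygosity == "HOM") # all truth sites are HET
  expect_true(abs(frac_hom - 0.1) < 0.015)

  clean <- simulate_chip(sim_config(genome_length = 200000L,
                                    n_variant_sites = 5000L,
                                    chip_site_fraction = 1,
                                    chip_het_to_hom_error = 0, seed = 17),
                         truth)
  i <- match(clean$key, truth$key)
  expect_true(all(clean$zygosity == truth$zygosity[i]))

  none <- simulate_chip(tiny_config(chip_site_fraction = 0, seed = 1),
                        truth)
  expect_equal(nrow(none), 0)
})

test_that("platform-specific suppression lands in repeats at the target rate", {
  cfg <- tiny_config(seed = 23)
  b <- simulate_all(cfg)
  rec <- classify_sites(b$p1$calls, b$p2$calls)
  for (cat in c("P1_SPECIFIC", "P2_SPECIFIC")) {
    ov <- repeat_overlap(rec, cat, b$genome$repeats)
    expect_true(abs(ov / 100 - cfg$repeat_enrichment) < 0.05,
                label = paste(cat, "repeat overlap", ov))
  }
})
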