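test_that("fst = 0 collapses every breed onto the ancestral frequencies", {
  pan <- simulate_panel(4, 50, fst = 0, seed = 120)
  p <- attr(pan, "ancestral")
  for (j in 1:4) expect_equal(unname(pan$freq[, j]), p, tolerance = 1e-12)
})

test_that("panel simulation is reproducible and validates fst", {
  p1 <- simulate_panel(3, 200, fst = 0.1, seed = 121)
  p2 <- simulate_panel(3, 200, fst = 0.1, seed = 121)
  expect_identical(p1$freq, p2$freq)
  expect_identical(p1$alleles, p2$alleles)
  p3 <- simulate_panel(3, 200, fst = 0.1, seed = 122)
  expect_false(identical(p1$freq, p3$freq))
  expect_error(simulate_panel(3, 200, fst = 1), "\\[0, 1\\)")
  expect_error(simulate_panel(3, 200, fst = -0.1), "\\[0, 1\\)")
})

test_that("breed frequencies have the Balding-Nichols variance around the ancestor", {
  fst <- 0.1
  pan <- simulate_panel(1, 20000, fst = fst, seed = 123,
                        ancestral_range = c(0.2, 0.8))
  p <- attr(pan, "ancestral")
  q <- pan$freq[, 1]
  # bin by ancestral frequency and compare empirical to model variance
  bins <- cut(p, seq(0.2, 0.8, by = 0.1))
  emp <- tapply((q - p)^2, bins, mean)
  mod <- tapply(fst * p * (1 - p), bins, mean)
  expect_true(all(abs(emp / mod - 1) < 0.1))
})

test_that("genotypes follow the binomial mixing model", {
  # near-degenerate frequencies give (at the fixed seed) deterministic calls
  pan <- reference_panel(matrix(c(0.999999, 0.000001), 2, 1,
                                dimnames = list(c("s1", "s2"), "b")),
                         clamp = 1e-6)
  g <- simulate_genotypes(pan, 1, 10, seed = 124)
  expect_true(all(unclass(g)[, 1] == 2))
  expect_true(all(unclass(g)[, 2] == 0))

  # moment check at one SNP
  pan2 <- reference_panel(cbind(b1 = 0.7, b2 = 0.2))
  gg <- simulate_genotypes(pan2, c(0.5, 0.5), 10000, seed = 125)
  f <- 0.45
  se <- sqrt(2 * f * (1 - f) / 10000)
  expect_lt(abs(mean(unclass(gg)[, 1]) - 2 * f), 3 * se)

  # no missingness unless requested; requested rate is honored
  expect_false(anyNA(unclass(gg)))
  gm <- simulate_genotypes(pan2, c(0.5, 0.5), 2000, seed = 126,
                           missing_rate = 0.1)
  expect_gt(mean(is.na(unclass(gm))), 0.07)
  expect_lt(mean(is.na(unclass(gm))), 0.13)

  expect_error(simulate_genotypes(pan2, c(0.5, 0.6), 5, seed = 1), "sum to 1")
  expect_error(simulate_genotypes(pan2, c(0.5, 0.5, 0), 5, seed = 1),
               "one entry per")
})

test_that("simulated purebreds pass the curation screen at the default cutoff", {
  pan <- simulate_panel(3, 2000, fst = 0.05, seed = 127)
  g <- simulate_genotypes(pan, c(1, 0, 0), 100, seed = 128,
                          breed = "breed_1")
  res <- curate_reference(g, cutoff = 2)
  expect_gte(mean(!res$report$excluded), 0.99)
})

test_that("fixture suites are deterministic, truthful, and round-trip exactly", {
  dir1 <- withr::local_tempdir()
  dir2 <- withr::local_tempdir()
  p1 <- make_fixture_suite(dir1, "composite_brangus_like", seed = 3,
                           n_snps = 300, n_test = 8)
  p2 <- make_fixture_suite(dir2, "composite_brangus_like", seed = 3,
                           n_snps = 300, n_test = 8)
  for (nm in names(p1))
    expect_identical(readLines(p1[[nm]]), readLines(p2[[nm]]))

  truth <- read.delim(p1$truth)
  expect_true(all(truth$angus_like == 0.625))
  expect_true(all(truth$brahman_like == 0.375))

  # purebred truth files contain only vertex rows
  p3 <- make_fixture_suite(withr::local_tempdir(), "purebred_id", seed = 4,
                           n_snps = 100, n_test = 3)
  tr <- as.matrix(read.delim(p3$truth)[, -1])
  expect_true(all(tr %in% c(0, 1)))
  expect_true(all(rowSums(tr) == 1))

  # PED/MAP round trip reproduces the in-memory genotypes exactly
  pan <- read_freq_table(p1$freq)
  g_in <- read_ped_map(p1$ped, p1$map, alleles = pan$alleles)
  pan_sim <- simulate_panel(4, 300, fst = 0.1, seed = 3,
                            breeds = c("angus_like", "brahman_like",
                                       "other_1", "other_2"))
  truth_m <- matrix(rep(c(0.625, 0.375, 0, 0), each = 8), 8)
  g_mem <- simulate_genotypes(pan_sim, truth_m, seed = 4)
  expect_identical(unclass(g_in)[, ], unclass(g_mem)[, ])
})

test_that("contamination scenario mixes purebreds with progressive crosses", {
  p <- make_fixture_suite(withr::local_tempdir(),
                          "limousin_like_contamination", seed = 8,
                          n_snps = 100, n_test = 4)
  tr <- read.delim(p$truth)
  expect_setequal(unique(tr$limousin_like), c(1, 0.5, 0.75, 0.875))
  br <- read.delim(p$breeds)
  expect_true(all(br$breed == "limousin_like"))
})
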