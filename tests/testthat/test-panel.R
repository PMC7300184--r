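test_that("allele frequencies are the A-allele count over non-missing calls", {
  g <- snp_genotypes(matrix(c(2, 1, 0, 1), 4, 1,
                            dimnames = list(paste0("a", 1:4), "s1")),
                     breed = rep("X", 4))
  pan <- allele_freq_panel(g)
  expect_equal(unname(pan$freq[1, 1]), 0.5)
  # monomorphic SNP is clamped away from the boundary
  g2 <- snp_genotypes(matrix(2, 4, 1, dimnames = list(paste0("a", 1:4), "s1")),
                      breed = rep("X", 4))
  expect_equal(unname(allele_freq_panel(g2)$freq[1, 1]), 1 - 1e-6)
  # missing calls drop out of the denominator
  g3 <- snp_genotypes(matrix(c(2, NA, 0, 2), 4, 1), breed = rep("X", 4))
  expect_equal(unname(allele_freq_panel(g3)$freq[1, 1]), 4 / 6)
})

test_that("estimated frequencies converge to the generating ones", {
  set.seed(71)
  n <- 10000
  g <- snp_genotypes(matrix(rbinom(n, 2, 0.3), n, 1), breed = rep("X", n))
  q <- unname(allele_freq_panel(g)$freq[1, 1])
  expect_lt(abs(q - 0.3), 0.01)
  # within 3 binomial standard errors
  expect_lt(abs(q - 0.3), 3 * sqrt(0.3 * 0.7 / (2 * n)))
})

test_that("panel construction validates groups and missing SNPs", {
  g <- snp_genotypes(matrix(c(2, 1, NA, NA), 2, 2,
                            dimnames = list(c("a1", "a2"), c("s1", "s2"))),
                     breed = c("X", "X"))
  expect_error(allele_freq_panel(g), "s2 has no non-missing calls in breed X")
  expect_error(allele_freq_panel(snp_genotypes(matrix(1, 1, 1)), breed = "Y"),
               NA)
  expect_error(reference_panel(matrix(1.2, 1, 1)), "\\[0, 1\\]")
  expect_error(reference_panel(matrix(numeric(0), 0, 1)), "at least one")
})

test_that("membership score has the closed form, order invariance, and additivity", {
  # one SNP at q = 0.5: HWE class probabilities (0.25, 0.5, 0.25)
  pan <- reference_panel(matrix(0.5, 1, 1, dimnames = list("s1", "B")))
  g <- snp_genotypes(matrix(1, 1, 1, dimnames = list("a1", "s1")))
  expect_equal(unname(membership_score(g, pan, "B", mode = "hwe")),
               -2 * log(0.5), tolerance = 1e-12)
  expect_equal(unname(membership_score(g, pan, "B", mode = "hwe")),
               1.3863, tolerance = 1e-4)

  # a genotype whose observed class has probability ~1 scores ~0
  cls <- array(c(1e-12, 1e-12, 1 - 2e-12), c(1, 1, 3))
  pan1 <- reference_panel(matrix(0.9, 1, 1, dimnames = list("s1", "B")),
                          class_freq = cls)
  g2 <- snp_genotypes(matrix(2, 1, 1, dimnames = list("a1", "s1")))
  expect_equal(unname(membership_score(g2, pan1, "B")), 0, tolerance = 1e-9)

  # permutation invariance and additivity over disjoint subsets
  pan5 <- simulate_panel(2, 40, fst = 0.1, seed = 72)
  gg <- simulate_genotypes(pan5, c(1, 0), 1, seed = 73)
  s_all <- membership_score(gg, pan5, "breed_1", mode = "hwe",
                            normalization = "total")
  perm <- sample(40)
  gg_perm <- gg[, perm, drop = FALSE]
  s_perm <- membership_score(gg_perm, pan5, "breed_1", mode = "hwe",
                             normalization = "total")
  expect_equal(s_all, s_perm, tolerance = 1e-10)
  pan_a <- reference_panel(pan5$freq[1:15, , drop = FALSE])
  pan_b <- reference_panel(pan5$freq[16:40, , drop = FALSE])
  s_a <- membership_score(gg[, 1:15, drop = FALSE], pan_a, "breed_1",
                          mode = "hwe", normalization = "total")
  s_b <- membership_score(gg[, 16:40, drop = FALSE], pan_b, "breed_1",
                          mode = "hwe", normalization = "total")
  expect_equal(unname(s_a + s_b), unname(s_all), tolerance = 1e-10)
})

test_that("membership scoring rejects unknown breeds and all-missing animals", {
  pan <- tiny_panel()
  g <- snp_genotypes(matrix(c(NA_integer_, NA_integer_), 1, 2,
                            dimnames = list("a1", pan$snp_ids)))
  expect_error(membership_score(g, pan, "b1", mode = "hwe"), "missing")
  g2 <- snp_genotypes(matrix(c(1L, 1L), 1, 2,
                             dimnames = list("a1", pan$snp_ids)))
  expect_error(membership_score(g2, pan, "nope", mode = "hwe"), "unknown breed")
})

test_that("curation retains everything at an infinite cutoff and is deterministic", {
  pan <- simulate_panel(2, 300, fst = 0.1, seed = 74)
  g <- simulate_genotypes(pan, c(1, 0), 30, seed = 75, breed = "breed_1")
  res <- curate_reference(g, cutoff = Inf)
  expect_equal(nrow(res$genotypes), 30)
  expect_false(any(res$report$excluded))
  # identical animals get identical scores
  codes <- unclass(g)
  dup <- snp_genotypes(rbind(codes[1, , drop = FALSE],
                             codes[1, , drop = FALSE]),
                       animal_ids = c("d1", "d2"),
                       snp_ids = colnames(g), breed = c("breed_1", "breed_1"))
  sc <- membership_score(dup, res$panel, "breed_1")
  expect_identical(unname(sc[1]), unname(sc[2]))
})

test_that("injected crossbreds rank highest and are excludable by a separating cutoff", {
  pan <- simulate_panel(3, 2000, fst = 0.1, seed = 76)
  pure <- simulate_genotypes(pan, c(1, 0, 0), 200, seed = 77, prefix = "pure")
  cross <- simulate_genotypes(pan, c(0.5, 0.5, 0), 20, seed = 78,
                              prefix = "cross")
  all_g <- snp_genotypes(rbind(unclass(pure), unclass(cross)),
                         breed = rep("breed_1", 220))
  scr <- curate_reference(all_g, cutoff = Inf)$report$score
  expect_true(all(rank(-scr)[201:220] <= 20))
  # the two score distributions separate, so a cutoff between them works
  gap_cut <- (max(scr[1:200]) + min(scr[201:220])) / 2
  expect_gt(min(scr[201:220]), max(scr[1:200]))
  res <- curate_reference(all_g, cutoff = gap_cut)
  expect_identical(sum(res$report$excluded), 20L)
  expect_true(all(grepl("^cross", res$report$animal_id[res$report$excluded])))
})

test_that("a second screening pass against the frozen panel removes nothing", {
  pan <- simulate_panel(2, 500, fst = 0.1, seed = 79)
  g <- simulate_genotypes(pan, c(1, 0), 40, seed = 80, breed = "breed_1")
  first <- curate_reference(g, cutoff = 2)
  second <- curate_reference(first$genotypes, cutoff = 2,
                             panel = first$panel)
  expect_false(any(second$report$excluded))
  expect_identical(nrow(second$genotypes), nrow(first$genotypes))
})

test_that("curation errors when a whole breed would be excluded", {
  pan <- simulate_panel(2, 200, fst = 0.1, seed = 81)
  g <- simulate_genotypes(pan, c(1, 0), 5, seed = 82, breed = "breed_1")
  expect_error(curate_reference(g, cutoff = 1e-6), "larger cutoff")
})
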