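test_that("conditional GBC renormalizes exactly over the ancestral subset", {
  gbc <- rbind(a1 = c(0.55, 0.25, 0.15, 0.05))
  colnames(gbc) <- c("AN", "BR", "HH", "LM")
  cond <- conditional_gbc(gbc, c("AN", "BR"))
  expect_equal(unname(cond[1, ]), c(0.6875, 0.3125))
  expect_equal(sum(cond[1, ]), 1)

  # already confined to the subset: identity
  gbc2 <- rbind(a1 = c(0.6, 0.4, 0, 0))
  colnames(gbc2) <- colnames(gbc)
  expect_equal(unname(conditional_gbc(gbc2, c("AN", "BR"))[1, ]),
               c(0.6, 0.4))

  # degenerate single-breed subset
  expect_equal(unname(conditional_gbc(gbc, "AN")[1, ]), 1)

  gbc3 <- rbind(a1 = c(0, 0, 0.5, 0.5))
  colnames(gbc3) <- colnames(gbc)
  expect_error(conditional_gbc(gbc3, c("AN", "BR")), "zero GBC mass.*a1")
  expect_error(conditional_gbc(gbc, c("AN", "XX")), "not among")
})

test_that("composite summaries average per-animal ratios, not ratios of means", {
  gbc <- rbind(c(0.5, 0.5, 0), c(0.9, 0.0, 0.1))
  colnames(gbc) <- c("A", "B", "C")
  cond <- conditional_gbc(gbc, c("A", "B"))
  s <- summarize_composite(cond)
  expect_equal(s$mean, c(75, 25))
  # the ratio-of-means convention would give a different answer
  rom <- 100 * colMeans(gbc[, c("A", "B")]) / sum(colMeans(gbc[, c("A", "B")]))
  expect_equal(unname(rom), c(73.68421, 26.31579), tolerance = 1e-5)
  expect_false(isTRUE(all.equal(s$mean, unname(rom))))

  s2 <- summarize_composite(rbind(c(A = 0.6, B = 0.4), c(A = 0.8, B = 0.2)))
  expect_equal(s2$mean, c(70, 30))
  # identical animals have zero dispersion
  s3 <- summarize_composite(rbind(c(A = 0.7, B = 0.3), c(A = 0.7, B = 0.3)))
  expect_equal(s3$sd, c(0, 0))
})

test_that("restricted-reference estimation works on a sub-panel", {
  pan <- simulate_panel(4, 300, fst = 0.12, seed = 110)
  g <- simulate_genotypes(pan, c(0.6, 0.4, 0, 0), 4, seed = 111)
  fit <- admix_fit_restricted(g, pan, c("breed_1", "breed_2"))
  expect_identical(colnames(coef(fit)), c("breed_1", "breed_2"))
  expect_simplex(coef(fit))
  # one-breed restriction is the trivial fit
  fit1 <- admix_fit_restricted(g, pan, "breed_1")
  expect_identical(unname(coef(fit1)[, 1]), rep(1, 4))
})

test_that("restricted and conditional estimates agree when mass stays inside the subset", {
  pan <- simulate_panel(3, 1500, fst = 0.2, seed = 112)
  g <- simulate_genotypes(pan, c(0.7, 0.3, 0), 6, seed = 113)
  full <- admix_fit(g, pan, "mcp")
  inside <- coef(full)[, "breed_3"] == 0
  expect_true(any(inside))  # strong differentiation zeroes the third breed
  cond <- conditional_gbc(full, c("breed_1", "breed_2"))
  restr <- admix_fit_restricted(g, pan, c("breed_1", "breed_2"),
                                penalty = "mcp")
  expect_equal(cond[inside, ], coef(restr)[inside, ], tolerance = 1e-4)
})

test_that("the restricted ML estimator recovers a known composite mixture", {
  pan <- simulate_panel(2, 1000, fst = 0.15, seed = 114,
                        breeds = c("angus_like", "brahman_like"))
  g <- simulate_genotypes(pan, c(0.625, 0.375), 50, seed = 115)
  fit <- admix_fit(g, pan, "none")
  bias <- colMeans(coef(fit)) - c(0.625, 0.375)
  expect_lt(max(abs(bias)), 0.02)
  # penalized estimation pulls toward the major vertex, never below ML
  fitm <- admix_fit(g, pan, "mcp")
  expect_gte(mean(coef(fitm)[, 1]), mean(coef(fit)[, 1]) - 1e-9)
})
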