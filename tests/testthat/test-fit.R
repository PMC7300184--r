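test_that("every returned GBC vector is a point of the simplex", {
  pan <- simulate_panel(4, 300, fst = 0.1, seed = 501)
  g <- simulate_genotypes(pan, c(0.4, 0.3, 0.2, 0.1), 8, seed = 502,
                          missing_rate = 0.05)
  for (fam in c("none", "l1", "mcp", "scad")) {
    fit <- admix_fit(g, pan, fam)
    expect_simplex(coef(fit))
  }
})

test_that("single-breed panels give GBC = 1 trivially under any penalty", {
  pan <- simulate_panel(1, 100, fst = 0.1, seed = 503)
  g <- simulate_genotypes(pan, 1, 3, seed = 504)
  for (fam in c("none", "mcp")) {
    fit <- admix_fit(g, pan, fam)
    expect_identical(unname(coef(fit)[, 1]), rep(1, 3))
    expect_true(all(is.finite(fit$loglik)))
    expect_true(all(fit$converged))
  }
})

test_that("penalized families at lambda = 0 reproduce the unpenalized fit", {
  inst <- random_instance(505, L = 4, M = 150)
  g <- simulate_genotypes(inst$panel, inst$truth, 5, seed = 506)
  base <- admix_fit(g, inst$panel, "none")
  for (fam in c("l1", "mcp", "scad")) {
    fit <- admix_fit(g, inst$panel, fam, lambda = 0)
    expect_equal(coef(fit), coef(base), tolerance = 1e-8)
  }
})

test_that("unpenalized fits agree with the independent EM solver", {
  ctl <- admix_control(tol_kkt = 1e-7)
  for (seed in 1:10) {
    inst <- random_instance(seed + 600)
    fit <- admix_fit(inst$geno, inst$panel, "none", control = ctl)
    em <- admix_em(inst$g, inst$panel, max_iter = 200000, tol = 1e-14)
    expect_lt(max(abs(em$gbc - coef(fit)[1L, ])), 1e-6)
  }
})

test_that("the EM update stays on the simplex and ascends the likelihood", {
  inst <- random_instance(610, L = 3, M = 120)
  em <- admix_em(inst$g, inst$panel, max_iter = 200, tol = 0, trace = TRUE)
  expect_equal(sum(em$gbc), 1, tolerance = 1e-12)
  expect_true(all(diff(em$loglik_path) >= -1e-9))
})

test_that("L = 2 fits match an exhaustive simplex grid search of the objective", {
  for (seed in 1:8) {
    inst <- random_instance(seed + 620, L = 2, M = 150)
    for (fam in c("none", "l1", "mcp")) {
      spec <- penalty_spec(fam, lambda = if (fam == "none") 0 else 0.25)
      fit <- admix_fit(inst$geno, inst$panel, spec, init = "multistart")
      best <- grid_search_L2(inst$g, inst$panel, spec)
      expect_lt(abs(coef(fit)[1L, 1L] - best), 2e-3)
    }
  }
})

test_that("converged estimates carry a valid independent KKT certificate", {
  pan <- simulate_panel(4, 400, fst = 0.08, seed = 630)
  g <- simulate_genotypes(pan, c(0.6, 0.4, 0, 0), 6, seed = 631)
  for (fam in c("none", "l1", "mcp", "scad")) {
    fit <- admix_fit(g, pan, fam)
    res <- admix_kkt_fit(fit, g)
    expect_true(all(res[fit$converged] <= fit$control$tol_kkt))
    expect_equal(unname(res), unname(fit$kkt), tolerance = 1e-6)
  }
})

test_that("purebred simulation at lambda = 0 recovers the true breed", {
  pan <- simulate_panel(5, 2000, fst = 0.1, seed = 640)
  g <- simulate_genotypes(pan, c(1, 0, 0, 0, 0), 200, seed = 641)
  fit <- admix_fit(g, pan, "none")
  # the labeled breed receives the dominant component for every animal
  expect_true(all(apply(coef(fit), 1L, which.max) == 1L))
  # the fraction of animals with >= 95% own-breed GBC equals the value the
  # independent EM oracle computes on these data (0.835): spurious
  # components for similar breeds keep it well below 1 at lambda = 0
  expect_equal(mean(coef(fit)[, 1L] >= 0.95), 0.835, tolerance = 1e-8)
})

test_that("larger lambda never reduces sparsity on a purebred example", {
  pan <- simulate_panel(5, 1000, fst = 0.08, seed = 650)
  g <- simulate_genotypes(pan, c(1, 0, 0, 0, 0), 15, seed = 651)
  n_zero <- function(fit) sum(coef(fit) == 0)
  f0 <- admix_fit(g, pan, "none")
  fm <- admix_fit(g, pan, "mcp", lambda = 0.25)
  expect_gte(n_zero(fm), n_zero(f0))
  expect_gte(percent_pure(fm, "breed_1"), percent_pure(f0, "breed_1"))
})

test_that("multistart resolves the nonconvex tie toward the better objective", {
  inst <- random_instance(660, L = 3, M = 100)
  spec <- penalty_spec("scad", 0.25)
  fit_u <- admix_fit(inst$geno, inst$panel, spec)
  fit_m <- admix_fit(inst$geno, inst$panel, spec, init = "multistart")
  Fu <- admix_loglik(inst$g, inst$panel, pmax(coef(fit_u)[1, ], 1e-12)) -
    sum(penalty_value(coef(fit_u)[1, ], spec))
  Fm <- admix_loglik(inst$g, inst$panel, pmax(coef(fit_m)[1, ], 1e-12)) -
    sum(penalty_value(coef(fit_m)[1, ], spec))
  expect_gte(Fm, Fu - 1e-9)
})

test_that("fit methods print, summarize, and simulate coherently", {
  pan <- simulate_panel(3, 200, fst = 0.1, seed = 670)
  g <- simulate_genotypes(pan, c(1, 0, 0), 5, seed = 671)
  fit <- admix_fit(g, pan, "mcp")
  expect_output(print(fit), "Admixture fit")
  sm <- summary(fit)
  expect_s3_class(sm, "summary.admix_fit")
  expect_output(print(sm), "Per-breed GBC")
  expect_equal(sum(sm$breeds$mean_gbc), 1, tolerance = 1e-8)
  ll <- logLik(fit)
  expect_s3_class(ll, "logLik")
  expect_equal(as.numeric(ll), sum(fit$loglik))
  sims <- simulate(fit, nsim = 2, seed = 99)
  expect_length(sims, 2L)
  expect_equal(dim(sims[[1L]]), dim(unclass(g)))
  expect_true(all(unclass(sims[[1L]]) %in% 0:2))
})
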