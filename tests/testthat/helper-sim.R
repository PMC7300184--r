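# Shared fixture builders; everything is generated in code at test time.

# tiny two-breed, two-SNP panel with hand-chosen frequencies
tiny_panel <- function() {
  reference_panel(cbind(b1 = c(0.8, 0.2), b2 = c(0.4, 0.6)))
}

# one random estimation instance (panel + one admixed animal) at small size
random_instance <- function(seed, L = NULL, M = NULL, fst = 0.15) {
  set.seed(seed)
  L <- L %||% sample(2:5, 1)
  M <- M %||% sample(50:200, 1)
  pan <- simulate_panel(L, M, fst = fst, seed = seed * 2L + 1L)
  w <- stats::rgamma(L, 1)
  w <- w / sum(w)
  g <- simulate_genotypes(pan, w, n_animals = 1, seed = seed * 2L + 2L)
  list(panel = pan, geno = g, g = unclass(g)[1L, ], truth = w,
       L = L, M = M)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# exhaustive 1-D simplex grid search of the penalized objective for L = 2
grid_search_L2 <- function(g, panel, spec, step = 0.001) {
  x1 <- seq(0, 1, by = step)
  f <- panel$freq %*% rbind(x1, 1 - x1)
  obs <- !is.na(g)
  ll <- colSums(g[obs] * log(f[obs, , drop = FALSE]) +
                  (2 - g[obs]) * log1p(-f[obs, , drop = FALSE]))
  pen <- vapply(x1, function(a) sum(penalty_value(c(a, 1 - a), spec)),
                numeric(1))
  x1[which.max(ll - pen)]
}

expect_simplex <- function(gbc, tol = 1e-8) {
  expect_true(all(gbc >= 0))
  expect_true(all(abs(rowSums(gbc) - 1) <= tol))
}
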