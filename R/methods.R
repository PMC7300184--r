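#' @export
print.admix_fit <- function(x, ...) {
  cat(sprintf("Admixture fit: %d animal(s), %d reference breed(s)\n",
              nrow(x$gbc), length(x$breeds)))
  print(x$penalty)
  cat(sprintf("Converged: %d/%d (max KKT residual %.3g)\n",
              sum(x$converged), length(x$converged), max(x$kkt)))
  n_show <- min(nrow(x$gbc), 6L)
  cat("Estimated GBC", if (nrow(x$gbc) > n_show) " (first 6 animals)", ":\n",
      sep = "")
  print(round(x$gbc[seq_len(n_show), , drop = FALSE], 4))
  invisible(x)
}

#' Summarize an admixture fit
#'
#' Per-breed means and standard deviations of the estimated GBC, the
#' number of animals called pure (GBC exactly 1) for each breed, and
#' convergence diagnostics.
#'
#' @param object an `"admix_fit"`.
#' @param ... unused.
#' @return An object of class `"summary.admix_fit"`.
#' @export
summary.admix_fit <- function(object, ...) {
  gbc <- object$gbc
  tab <- data.frame(
    breed = object$breeds,
    mean_gbc = colMeans(gbc),
    sd_gbc = apply(gbc, 2L, stats::sd),
    n_pure = colSums(gbc >= 1 - 1e-6),
    pct_pure = 100 * colMeans(gbc >= 1 - 1e-6),
    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(penalty = object$penalty, breeds = tab,
                 n_animals = nrow(gbc),
                 n_converged = sum(object$converged),
                 mean_loglik = mean(object$loglik),
                 mean_iter = mean(object$n_iter),
                 max_kkt = max(object$kkt)),
            class = "summary.admix_fit")
}

#' @export
print.summary.admix_fit <- function(x, ...) {
  cat(sprintf("Admixture fit over %d animal(s)\n", x$n_animals))
  print(x$penalty)
  cat(sprintf("Converged %d/%d; mean iterations %.1f; max KKT residual %.3g\n",
              x$n_converged, x$n_animals, x$mean_iter, x$max_kkt))
  cat(sprintf("Mean log-likelihood per animal: %.3f\n", x$mean_loglik))
  cat("Per-breed GBC:\n")
  tb <- x$breeds
  tb$mean_gbc <- round(tb$mean_gbc, 4)
  tb$sd_gbc <- round(tb$sd_gbc, 4)
  tb$pct_pure <- round(tb$pct_pure, 1)
  print(tb, row.names = FALSE)
  invisible(x)
}

#' @export
coef.admix_fit <- function(object, ...) object$gbc

#' @export
logLik.admix_fit <- function(object, ...) {
  val <- sum(object$loglik)
  attr(val, "df") <- sum(object$gbc > 0) - nrow(object$gbc)
  attr(val, "nobs") <- sum(object$n_snps_used)
  class(val) <- "logLik"
  val
}

#' Stacked-bar plot of estimated breed composition
#'
#' @param x an `"admix_fit"`.
#' @param max_animals cap on the number of animals drawn (default 100).
#' @param ... passed to [graphics::barplot()].
#' @return invisibly, the bar midpoints.
#' @export
plot.admix_fit <- function(x, max_animals = 100L, ...) {
  gbc <- x$gbc[seq_len(min(nrow(x$gbc), max_animals)), , drop = FALSE]
  mids <- graphics::barplot(t(gbc), col = seq_along(x$breeds) + 1L,
                            border = NA, space = 0,
                            ylab = "estimated GBC",
                            xlab = "animal",
                            legend.text = x$breeds,
                            args.legend = list(x = "topright", bg = "white",
                                               cex = 0.8), ...)
  invisible(mids)
}

#' Simulate genotypes from a fitted admixture model
#'
#' Draws new genotype matrices from the fitted model: each simulated
#' animal's genotypes are Binomial(2, f) at every SNP, with f the
#' admixture-weighted allele frequency implied by that animal's estimated
#' GBC and the fit's reference panel.
#'
#' @param object an `"admix_fit"`.
#' @param nsim number of replicate genotype matrices.
#' @param seed integer seed (optional).
#' @param ... unused.
#' @return A list of `nsim` [snp_genotypes()] matrices, each with one row
#'   per fitted animal.
#' @export
simulate.admix_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  q <- object$panel$freq
  lapply(seq_len(nsim), function(r) {
    f <- q %*% t(object$gbc)               # M x animals
    codes <- matrix(stats::rbinom(length(f), 2L, as.vector(f)),
                    nrow = ncol(f), ncol = nrow(f), byrow = TRUE)
    snp_genotypes(codes, animal_ids = object$animal_ids,
                  snp_ids = object$panel$snp_ids)
  })
}
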