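gbc_matrix <- function(x) {
  if (inherits(x, "admix_fit")) x$gbc
  else if (is.matrix(x)) x
  else stop("expected an 'admix_fit' or a GBC matrix", call. = FALSE)
}

#' Percent of animals called pure for a breed
#'
#' The power criterion for purebred identification: the percentage of
#' animals whose estimated GBC for the labeled breed equals 1 (within
#' 1e-6, i.e. after the optimizer's exact-zero clipping a purebred call is
#' exact).
#'
#' @param x an `"admix_fit"` or a GBC matrix with breed column names.
#' @param breed breed label (must be a column of the GBC matrix).
#' @return A percentage in \[0, 100\].
#' @export
percent_pure <- function(x, breed) {
  gbc <- gbc_matrix(x)
  if (!nrow(gbc)) stop("no estimates supplied", call. = FALSE)
  if (!breed %in% colnames(gbc))
    stop("unknown breed label: ", breed, call. = FALSE)
  100 * mean(gbc[, breed] >= 1 - 1e-6)
}

#' Tabulate estimated GBC by category
#'
#' Histogram of one breed's estimated GBC over the eleven categories used
#' for purebred reporting: the pure class (GBC exactly 1) followed by the
#' half-open deciles \[0.9, 1), \[0.8, 0.9), ..., \[0, 0.1). The
#' percentages sum to 100.
#'
#' @inheritParams percent_pure
#' @return A data frame with columns `category` and `percent`, of class
#'   `"gbc_category_table"`.
#' @export
gbc_categories <- function(x, breed) {
  gbc <- gbc_matrix(x)
  if (!nrow(gbc)) stop("no estimates supplied", call. = FALSE)
  if (!breed %in% colnames(gbc))
    stop("unknown breed label: ", breed, call. = FALSE)
  v <- gbc[, breed]
  pure <- v >= 1 - 1e-6
  lo <- seq(0.9, 0, by = -0.1)
  counts <- c(sum(pure),
              vapply(lo, function(b)
                sum(!pure & v >= b & v < b + 0.1), numeric(1)))
  labels <- c("1", sprintf("[%.1f, %.1f)", lo, lo + 0.1))
  structure(data.frame(category = labels,
                       percent = 100 * counts / length(v),
                       stringsAsFactors = FALSE),
            class = c("gbc_category_table", "data.frame"),
            breed = breed, n = length(v))
}

#' Choose the regularization strength by cross-validation
#'
#' Selects \eqn{\lambda} for a penalized admixture model by k-fold
#' cross-validation on the percent-pure criterion, mirroring the procedure
#' used to tune the cattle models: the focal breed's reference animals are
#' randomly split into k subsets; for each rotation the focal breed's
#' allele frequencies are re-estimated from the k-1 training subsets
#' (all other breeds' frequencies stay fixed at their full-panel values),
#' GBC is estimated for the held-out animals at every \eqn{\lambda} in the
#' grid, and the percentage of held-out animals with GBC = 1 for the focal
#' breed is pooled over folds. The chosen \eqn{\lambda} maximizes the
#' pooled percent-pure, with ties broken toward the larger (sparser)
#' value.
#'
#' @param geno a [snp_genotypes()] matrix of the focal breed's reference
#'   animals.
#' @param panel the full [reference_panel()] (contains the focal breed).
#' @param breed focal breed label.
#' @param family penalty family (`"l1"`, `"mcp"`, `"scad"`, or `"none"`).
#' @param lambda_grid nonempty vector of candidate \eqn{\lambda} values;
#'   the default grid \{0, 0.05, ..., 0.6\} covers the optima and bounds
#'   reported for cattle.
#' @param k number of folds (default 3).
#' @param seed integer seed for the fold split.
#' @param gamma concavity parameter for MCP/SCAD.
#' @param control an [admix_control()].
#' @param pseudocount,clamp passed to the per-fold frequency estimation.
#' @return An object of class `"admix_cv"`: list with `lambda_grid`,
#'   `family`, `k`, `fold_pure` (k x length(grid) matrix of per-fold
#'   percent-pure), `pooled_pure`, `chosen_lambda`, `seed`, `folds`.
#' @export
cv_lambda <- function(geno, panel, breed, family = "mcp",
                      lambda_grid = c(0, 0.05, 0.1, 0.15, 0.2, 0.25,
                                      0.3, 0.4, 0.5, 0.6),
                      k = 3L, seed = 1L, gamma = 3,
                      control = admix_control(), pseudocount = 0.5,
                      clamp = NULL) {
  stopifnot(inherits(panel, "reference_panel"))
  if (!length(lambda_grid)) stop("'lambda_grid' is empty", call. = FALSE)
  if (k < 2L) stop("'k' must be at least 2", call. = FALSE)
  if (!breed %in% panel$breeds)
    stop("unknown breed label: ", breed, call. = FALSE)
  geno <- align_genotypes(geno, panel)
  n <- nrow(geno)
  if (n < k) stop("more folds than animals", call. = FALSE)
  clamp <- clamp %||% panel$clamp
  lambda_grid <- sort(unique(as.numeric(lambda_grid)))

  set.seed(seed)
  fold <- sample(rep_len(seq_len(k), n))
  jb <- match(breed, panel$breeds)
  pure <- matrix(0, k, length(lambda_grid))
  n_test <- integer(k)
  fold_freq <- matrix(NA_real_, length(panel$snp_ids), k,
                      dimnames = list(panel$snp_ids, NULL))
  for (f in seq_len(k)) {
    test <- which(fold == f)
    train <- which(fold != f)
    q_focal <- colSums(unclass(geno)[train, , drop = FALSE], na.rm = TRUE) /
      (2 * colSums(!is.na(unclass(geno)[train, , drop = FALSE])))
    q_focal <- pmin(pmax(q_focal, clamp), 1 - clamp)
    fold_freq[, f] <- q_focal
    freq <- panel$freq
    freq[, jb] <- q_focal
    fold_panel <- reference_panel(freq, clamp = clamp)
    n_test[f] <- length(test)
    for (li in seq_along(lambda_grid)) {
      fit <- admix_fit(geno[test, , drop = FALSE], fold_panel,
                       penalty = family, lambda = lambda_grid[li],
                       gamma = gamma, control = control)
      pure[f, li] <- percent_pure(fit, breed)
    }
  }
  pooled <- colSums(pure * n_test) / sum(n_test)
  best <- max(pooled)
  chosen <- max(lambda_grid[pooled >= best - 1e-12])  # tie -> sparser
  structure(list(lambda_grid = lambda_grid, family = family, k = k,
                 fold_pure = pure, pooled_pure = pooled,
                 chosen_lambda = chosen, seed = seed, folds = fold,
                 fold_freq = fold_freq, breed = breed),
            class = "admix_cv")
}

#' @export
print.admix_cv <- function(x, ...) {
  cat(sprintf("%d-fold cross-validation of lambda (%s penalty, breed %s)\n",
              x$k, x$family, x$breed))
  tb <- data.frame(lambda = x$lambda_grid,
                   pooled_pct_pure = round(x$pooled_pure, 2))
  print(tb, row.names = FALSE)
  cat(sprintf("Chosen lambda: %g\n", x$chosen_lambda))
  invisible(x)
}
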