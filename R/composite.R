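#' Conditional GBC over a declared ancestral subset
#'
#' For composite animals with known ancestral breeds (e.g. Brangus,
#' stabilized at 5/8 Angus and 3/8 Brahman), the full-panel GBC assigns
#' small components to non-ancestral breeds, so the ancestral components
#' do not add to 1. The conditional GBC renormalizes over the declared
#' ancestral subset: \eqn{x_j / \sum_{j' \in A} x_{j'}} for each ancestral
#' breed j, which can be read as the composition given that the ancestry
#' lies in the subset. Each animal's conditional vector sums to exactly 1.
#'
#' @param x an `"admix_fit"` or a GBC matrix with breed column names.
#' @param ancestral character vector of ancestral breed labels.
#' @return A matrix (animals x ancestral breeds) of conditional GBC.
#' @examples
#' gbc <- rbind(a1 = c(AN = 0.55, BR = 0.25, HH = 0.15, LM = 0.05))
#' conditional_gbc(gbc, c("AN", "BR"))  # 0.6875, 0.3125
#' @export
conditional_gbc <- function(x, ancestral) {
  gbc <- gbc_matrix(x)
  missing_b <- setdiff(ancestral, colnames(gbc))
  if (length(missing_b))
    stop("ancestral breed(s) not among estimates: ",
         paste(missing_b, collapse = ", "), call. = FALSE)
  sub <- gbc[, ancestral, drop = FALSE]
  tot <- rowSums(sub)
  zero <- tot <= 0
  if (any(zero))
    stop("zero GBC mass on the ancestral subset for animal(s): ",
         paste(utils::head(rownames(gbc)[zero], 5L), collapse = ", "),
         call. = FALSE)
  sub / tot
}

#' Restricted-reference estimation for composite animals
#'
#' Estimates GBC using only the declared ancestral breeds as the
#' reference: the panel is restricted to the subset and [admix_fit()] is
#' run on it, so the estimate is of the same dimension as the subset.
#' This is the alternative to [conditional_gbc()] for composite animals;
#' the two agree exactly whenever the full-panel estimate already places
#' zero mass outside the subset.
#'
#' @param geno genotypes (see [admix_fit()]).
#' @param panel the full [reference_panel()].
#' @param ancestral character vector of ancestral breed labels.
#' @inheritParams admix_fit
#' @return An `"admix_fit"` over the ancestral breeds only.
#' @export
admix_fit_restricted <- function(geno, panel, ancestral, penalty = "none",
                                 lambda = NULL, gamma = 3,
                                 control = admix_control(),
                                 init = "uniform") {
  sub <- subset_panel(panel, ancestral)
  admix_fit(geno, sub, penalty = penalty, lambda = lambda, gamma = gamma,
            control = control, init = init)
}

#' Mean and SD of estimated composition across animals
#'
#' Per-breed mean and standard deviation of per-animal GBC, on the 0-100
#' percent scale, as used to report composite breeds. For conditional
#' results the summaries are the mean and SD of the per-animal conditional
#' ratios (not the ratio of mean components, which is a different and, for
#' reporting purposes, inconsistent convention).
#'
#' @param x an `"admix_fit"`, a GBC matrix, or the matrix returned by
#'   [conditional_gbc()].
#' @return A data frame with columns `breed`, `mean`, `sd` (percent).
#' @examples
#' gbc <- rbind(c(a = 0.6, b = 0.4), c(a = 0.8, b = 0.2))
#' summarize_composite(gbc)  # means 70 and 30 percent
#' @export
summarize_composite <- function(x) {
  gbc <- gbc_matrix(x)
  if (!nrow(gbc)) stop("no estimates supplied", call. = FALSE)
  data.frame(breed = colnames(gbc),
             mean = 100 * colMeans(gbc),
             sd = 100 * apply(gbc, 2L, stats::sd),
             row.names = NULL, stringsAsFactors = FALSE)
}
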