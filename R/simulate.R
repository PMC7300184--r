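#' Simulate a differentiated breed reference panel
#'
#' Draws breed allele frequencies under the Balding-Nichols model: an
#' ancestral frequency \eqn{p_k} is drawn uniformly from
#' `ancestral_range` for each SNP, and each breed's frequency is drawn
#' independently from a Beta distribution with mean \eqn{p_k} and variance
#' \eqn{F_{ST}\, p_k(1-p_k)} (shape parameters
#' \eqn{p_k(1-F_{ST})/F_{ST}} and \eqn{(1-p_k)(1-F_{ST})/F_{ST}}).
#' `fst = 0` returns every breed identical to the ancestral frequencies.
#' Cattle breeds are moderately divergent (\eqn{F_{ST} < 0.10}), so
#' defaults in this range emulate the intended use case.
#'
#' The panel carries synthetic SNP annotation (chromosome, position,
#' alleles) so it can be written to PED/MAP and frequency files.
#'
#' @param n_breeds number of breeds L.
#' @param n_snps number of SNPs M.
#' @param fst differentiation parameter in \[0, 1).
#' @param ancestral_range range of the uniform ancestral frequency draw
#'   (default \[0.1, 0.9\]).
#' @param seed integer seed; the panel is bit-reproducible given the seed.
#' @param breeds optional breed labels (default `"breed_1"`, ...).
#' @param clamp frequency clamp passed to [reference_panel()].
#' @return A `"reference_panel"` whose attribute `"ancestral"` records the
#'   ancestral frequencies \eqn{p_k}.
#' @examples
#' pan <- simulate_panel(3, 100, fst = 0.05, seed = 1)
#' @export
simulate_panel <- function(n_breeds, n_snps, fst, ancestral_range = c(0.1, 0.9),
                           seed = 1L, breeds = NULL, clamp = 1e-6) {
  stopifnot(n_breeds >= 1L, n_snps >= 1L)
  if (!is.numeric(fst) || length(fst) != 1L || is.na(fst) || fst < 0 ||
      fst >= 1)
    stop("'fst' must lie in [0, 1)", call. = FALSE)
  stopifnot(length(ancestral_range) == 2L, ancestral_range[1L] > 0,
            ancestral_range[2L] < 1,
            ancestral_range[1L] <= ancestral_range[2L])
  breeds <- breeds %||% sprintf("breed_%d", seq_len(n_breeds))
  stopifnot(length(breeds) == n_breeds)
  set.seed(seed)
  p <- stats::runif(n_snps, ancestral_range[1L], ancestral_range[2L])
  freq <- matrix(NA_real_, n_snps, n_breeds,
                 dimnames = list(sprintf("snp_%d", seq_len(n_snps)), breeds))
  if (fst == 0) {
    freq[] <- p
  } else {
    shape_scale <- (1 - fst) / fst
    for (j in seq_len(n_breeds))
      freq[, j] <- stats::rbeta(n_snps, p * shape_scale,
                                (1 - p) * shape_scale)
  }
  base <- c("A", "C", "G", "T")
  a1 <- sample(base, n_snps, replace = TRUE)
  a2 <- vapply(a1, function(a) sample(setdiff(base, a), 1L), character(1))
  alleles <- data.frame(
    snp_id = rownames(freq),
    chrom = ((seq_len(n_snps) - 1L) %% 29L) + 1L,
    pos = 1000L * seq_len(n_snps),
    allele_a = a1, allele_b = unname(a2),
    stringsAsFactors = FALSE)
  pan <- reference_panel(freq, alleles = alleles, clamp = clamp)
  attr(pan, "ancestral") <- p
  pan
}

#' Simulate genotypes with known admixture
#'
#' Draws HWE genotypes for animals of known breed composition: each
#' animal's allele-A frequency at SNP k is the mixture
#' \eqn{f_k = \sum_j q_{jk} X_j} of the panel's breed frequencies, and the
#' genotype is Binomial(2, \eqn{f_k}). Optionally masks calls at random
#' to emulate missing genotypes. Drawing the two allele copies
#' independently by breed of origin is equivalent to this binomial mixing
#' under the model's own assumptions (independent loci, HWE), so no
#' pedigree machinery is involved and the data are LD-free by
#' construction.
#'
#' @param panel a [reference_panel()] (or a bare M x L frequency matrix).
#' @param admixture true mixture vector on the simplex (length L), or an
#'   n_animals x L matrix of per-animal mixtures.
#' @param n_animals number of animals (ignored when `admixture` is a
#'   matrix).
#' @param seed integer seed.
#' @param missing_rate per-call missingness probability in \[0, 1).
#' @param breed optional breed label(s) to attach to the animals.
#' @param prefix prefix for generated animal ids.
#' @return A [snp_genotypes()] matrix aligned to the panel's SNPs, with
#'   attribute `"true_admixture"` (n_animals x L matrix).
#' @export
simulate_genotypes <- function(panel, admixture, n_animals = 1L, seed = 1L,
                               missing_rate = 0, breed = NULL,
                               prefix = "animal") {
  q <- if (inherits(panel, "reference_panel")) panel$freq else as.matrix(panel)
  L <- ncol(q)
  if (is.null(dim(admixture))) {
    if (length(admixture) != L)
      stop("admixture vectors must have one entry per panel breed",
           call. = FALSE)
    admixture <- matrix(admixture, n_animals, L, byrow = TRUE)
  }
  admixture <- as.matrix(admixture)
  if (ncol(admixture) != L)
    stop("admixture vectors must have one entry per panel breed",
         call. = FALSE)
  if (any(admixture < 0) || any(abs(rowSums(admixture) - 1) > 1e-9))
    stop("each admixture vector must be nonnegative and sum to 1",
         call. = FALSE)
  if (missing_rate < 0 || missing_rate >= 1)
    stop("'missing_rate' must lie in [0, 1)", call. = FALSE)
  n_animals <- nrow(admixture)
  set.seed(seed)
  f <- q %*% t(admixture)                       # M x n_animals
  codes <- matrix(stats::rbinom(length(f), 2L, as.vector(f)),
                  nrow = n_animals, ncol = nrow(q), byrow = TRUE)
  if (missing_rate > 0)
    codes[stats::runif(length(codes)) < missing_rate] <- NA_integer_
  g <- snp_genotypes(codes,
                     animal_ids = sprintf("%s_%d", prefix,
                                          seq_len(n_animals)),
                     snp_ids = rownames(q),
                     breed = if (!is.null(breed)) rep_len(breed, n_animals))
  colnames(admixture) <- colnames(q)
  attr(g, "true_admixture") <- admixture
  g
}

#' Write a self-contained simulated fixture to disk
#'
#' Generates a complete, deterministic test scenario and writes it in the
#' package's standard file formats: a PED/MAP pair of test-animal
#' genotypes, a breed-assignment TSV, a breed allele-frequency TSV, and a
#' truth TSV giving each animal's simulated admixture vector.
#'
#' Scenarios:
#' \describe{
#'   \item{purebred_id}{five moderately divergent breeds; every test
#'     animal is a purebred (vertex truth).}
#'   \item{composite_brangus_like}{a four-breed panel in which the test
#'     animals are composites of the first two breeds at the 5/8 : 3/8
#'     design ratio of a stabilized Brangus-type breed.}
#'   \item{limousin_like_contamination}{one focal breed whose test set
#'     mixes purebreds with progressive crosses (1/2, 3/4, 7/8 grades)
#'     toward a second breed, emulating a contaminated reference.}
#' }
#'
#' @param dir output directory (created if needed).
#' @param scenario one of the three scenario names.
#' @param seed integer seed; all outputs are deterministic given it.
#' @param n_snps SNPs simulated (default 2000).
#' @param fst breed differentiation (default 0.1).
#' @param n_test test animals per truth group (default 50).
#' @return Invisibly, a named list of the file paths written (`ped`,
#'   `map`, `breeds`, `freq`, `truth`).
#' @export
make_fixture_suite <- function(dir,
                               scenario = c("purebred_id",
                                            "composite_brangus_like",
                                            "limousin_like_contamination"),
                               seed = 1L, n_snps = 2000L, fst = 0.1,
                               n_test = 50L) {
  scenario <- match.arg(scenario)
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
    stop("cannot create output directory: ", dir, call. = FALSE)
  cfg <- switch(scenario,
    purebred_id = {
      L <- 5L
      list(breeds = sprintf("breed_%d", 1:L),
           truth = diag(L))
    },
    composite_brangus_like = {
      list(breeds = c("angus_like", "brahman_like", "other_1", "other_2"),
           truth = matrix(c(0.625, 0.375, 0, 0), 1L))
    },
    limousin_like_contamination = {
      list(breeds = c("limousin_like", "angus_like", "other_1"),
           truth = rbind(c(1, 0, 0), c(0.5, 0.5, 0), c(0.75, 0.25, 0),
                         c(0.875, 0.125, 0)))
    })
  L <- length(cfg$breeds)
  panel <- simulate_panel(L, n_snps, fst, seed = seed, breeds = cfg$breeds)
  groups <- nrow(cfg$truth)
  truth <- cfg$truth[rep(seq_len(groups), each = n_test), , drop = FALSE]
  geno <- simulate_genotypes(panel, truth, seed = seed + 1L)
  label <- cfg$breeds[apply(truth, 1L, which.max)]
  paths <- list(ped = file.path(dir, paste0(scenario, ".ped")),
                map = file.path(dir, paste0(scenario, ".map")),
                breeds = file.path(dir, paste0(scenario, "_breeds.tsv")),
                freq = file.path(dir, paste0(scenario, "_freq.tsv")),
                truth = file.path(dir, paste0(scenario, "_truth.tsv")))
  write_ped_map(geno, paths$ped, paths$map, alleles = panel$alleles)
  write_tsv(data.frame(animal_id = rownames(geno), breed = label,
                       stringsAsFactors = FALSE), paths$breeds)
  write_freq_table(panel, paths$freq)
  tr <- data.frame(animal_id = rownames(geno),
                   format(truth, digits = 12, trim = TRUE, scientific = FALSE),
                   stringsAsFactors = FALSE)
  names(tr) <- c("animal_id", cfg$breeds)
  write_tsv(tr, paths$truth)
  invisible(paths)
}
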