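#' SNP genotype matrix container
#'
#' Wraps an animals-by-SNPs matrix of numeric genotype codes. Codes count
#' copies of allele A: 2 (AA), 1 (AB), 0 (BB); missing calls are `NA`.
#'
#' @param codes numeric matrix, animals in rows, SNPs in columns; entries in
#'   \{0, 1, 2, NA\}.
#' @param animal_ids,snp_ids character identifiers; default taken from
#'   `dimnames(codes)`, else generated.
#' @param breed optional character vector of breed labels, one per animal
#'   (used by panel construction and curation).
#' @return An object of class `"snp_genotypes"`: the integer matrix with
#'   row/column names and an optional `breed` attribute.
#' @export
snp_genotypes <- function(codes, animal_ids = NULL, snp_ids = NULL,
                          breed = NULL) {
  codes <- as.matrix(codes)
  ok <- is.na(codes) | codes == 0 | codes == 1 | codes == 2
  if (!all(ok)) {
    bad <- which(!ok, arr.ind = TRUE)[1L, ]
    stop(sprintf(
      "invalid genotype code %s at animal %d, SNP %d: codes must be 0, 1, 2 or NA",
      format(codes[bad[1L], bad[2L]]), bad[1L], bad[2L]), call. = FALSE)
  }
  storage.mode(codes) <- "integer"
  if (is.null(animal_ids))
    animal_ids <- rownames(codes) %||% sprintf("animal_%d", seq_len(nrow(codes)))
  if (is.null(snp_ids))
    snp_ids <- colnames(codes) %||% sprintf("snp_%d", seq_len(ncol(codes)))
  if (anyDuplicated(animal_ids)) stop("duplicate animal ids", call. = FALSE)
  if (anyDuplicated(snp_ids)) stop("duplicate SNP ids", call. = FALSE)
  dimnames(codes) <- list(animal_ids, snp_ids)
  if (!is.null(breed)) {
    if (length(breed) != nrow(codes))
      stop("'breed' must have one label per animal", call. = FALSE)
    attr(codes, "breed") <- as.character(breed)
  }
  class(codes) <- c("snp_genotypes", class(codes))
  codes
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.snp_genotypes <- function(x, ...) {
  cat(sprintf("SNP genotypes: %d animals x %d SNPs", nrow(x), ncol(x)))
  br <- attr(x, "breed")
  if (!is.null(br)) {
    tb <- table(br)
    cat(sprintf("; breeds: %s",
                paste(sprintf("%s (%d)", names(tb), tb), collapse = ", ")))
  }
  nmis <- sum(is.na(x))
  cat(sprintf("; missing calls: %d (%.2f%%)\n", nmis, 100 * nmis / length(x)))
  invisible(x)
}

#' @export
`[.snp_genotypes` <- function(x, i, j, ..., drop = FALSE) {
  br <- attr(x, "breed")
  cl <- class(x)
  y <- unclass(x)
  attr(y, "breed") <- NULL
  y <- y[i, j, ..., drop = drop]
  if (is.matrix(y)) {
    if (!is.null(br)) {
      names(br) <- rownames(x)
      attr(y, "breed") <- unname(br[rownames(y)])
    }
    class(y) <- cl
  }
  y
}

geno_breed <- function(geno, breed = NULL) {
  breed <- breed %||% attr(geno, "breed")
  if (is.null(breed))
    stop("breed labels required: supply 'breed' or construct the genotypes ",
         "with a breed attribute", call. = FALSE)
  if (length(breed) != nrow(geno))
    stop("'breed' must have one label per animal", call. = FALSE)
  as.character(breed)
}

#' Reference panel of breed allele frequencies
#'
#' A reference panel holds, for each of L breeds and M SNPs, the frequency
#' of allele A, and optionally the per-breed genotype-class (BB, AB, AA)
#' relative frequencies used for likelihood-based curation. Frequencies are
#' clamped to `[clamp, 1 - clamp]` so that every log term in the admixture
#' likelihood stays finite even at SNPs that are monomorphic within a breed.
#'
#' @param freq numeric M x L matrix of allele-A frequencies in \[0, 1\];
#'   SNPs in rows, breeds in columns (column names are the breed labels).
#' @param class_freq optional M x L x 3 array of genotype-class relative
#'   frequencies (classes BB, AB, AA in the third dimension); each
#'   (SNP, breed) triple must sum to 1.
#' @param n_animals optional named integer vector of per-breed reference
#'   counts.
#' @param alleles optional data frame with columns `snp_id`, `chrom`, `pos`,
#'   `allele_a`, `allele_b` describing the physical SNPs (used when writing
#'   PED/MAP or frequency tables).
#' @param clamp frequency clamp \eqn{\epsilon_f} (default 1e-6).
#' @return An object of class `"reference_panel"`.
#' @seealso [allele_freq_panel()] to estimate a panel from reference
#'   genotypes, [read_freq_table()] to load one from disk.
#' @export
reference_panel <- function(freq, class_freq = NULL, n_animals = NULL,
                            alleles = NULL, clamp = 1e-6) {
  freq <- as.matrix(freq)
  if (nrow(freq) < 1L || ncol(freq) < 1L)
    stop("panel must have at least one SNP and one breed", call. = FALSE)
  if (any(!is.finite(freq)) || any(freq < 0) || any(freq > 1))
    stop("allele frequencies must lie in [0, 1]", call. = FALSE)
  if (is.null(colnames(freq)))
    colnames(freq) <- sprintf("breed_%d", seq_len(ncol(freq)))
  if (is.null(rownames(freq)))
    rownames(freq) <- sprintf("snp_%d", seq_len(nrow(freq)))
  if (anyDuplicated(colnames(freq))) stop("duplicate breed labels", call. = FALSE)
  if (anyDuplicated(rownames(freq))) stop("duplicate SNP ids", call. = FALSE)
  stopifnot(clamp > 0, clamp < 0.5)
  freq <- pmin(pmax(freq, clamp), 1 - clamp)
  if (!is.null(class_freq)) {
    stopifnot(length(dim(class_freq)) == 3L,
              dim(class_freq)[1L] == nrow(freq),
              dim(class_freq)[2L] == ncol(freq),
              dim(class_freq)[3L] == 3L)
    sums <- apply(class_freq, c(1L, 2L), sum)
    if (any(abs(sums - 1) > 1e-9))
      stop("genotype-class frequencies must sum to 1 per breed and SNP",
           call. = FALSE)
    dimnames(class_freq) <- list(rownames(freq), colnames(freq),
                                 c("BB", "AB", "AA"))
  }
  structure(list(breeds = colnames(freq), snp_ids = rownames(freq),
                 freq = freq, class_freq = class_freq,
                 n_animals = n_animals, alleles = alleles, clamp = clamp),
            class = "reference_panel")
}

#' @export
print.reference_panel <- function(x, ...) {
  cat(sprintf("Reference panel: %d breeds x %d SNPs\n",
              length(x$breeds), length(x$snp_ids)))
  cat("Breeds:", paste(x$breeds, collapse = ", "), "\n")
  if (!is.null(x$n_animals))
    cat("Reference animals:",
        paste(sprintf("%s=%d", names(x$n_animals), x$n_animals),
              collapse = ", "), "\n")
  cat(sprintf("Mean allele-A frequency per breed: %s\n",
              paste(sprintf("%.3f", colMeans(x$freq)), collapse = ", ")))
  invisible(x)
}

#' @export
dim.reference_panel <- function(x) c(length(x$snp_ids), length(x$breeds))

#' Restrict a panel to a subset of breeds
#'
#' @param panel a [reference_panel()].
#' @param breeds character vector of breed labels to keep (order preserved
#'   as given).
#' @return A `"reference_panel"` over the selected breeds.
#' @export
subset_panel <- function(panel, breeds) {
  stopifnot(inherits(panel, "reference_panel"))
  missing_b <- setdiff(breeds, panel$breeds)
  if (length(missing_b))
    stop("breed(s) not in panel: ", paste(missing_b, collapse = ", "),
         call. = FALSE)
  idx <- match(breeds, panel$breeds)
  reference_panel(panel$freq[, idx, drop = FALSE],
                  class_freq = if (!is.null(panel$class_freq))
                    panel$class_freq[, idx, , drop = FALSE],
                  n_animals = panel$n_animals[breeds],
                  alleles = panel$alleles, clamp = panel$clamp)
}

#' Align genotypes to a panel's SNP order
#'
#' Reorders (and restricts) the genotype columns so they match the panel's
#' SNP identifiers; errors if the panel contains SNPs absent from the
#' genotypes.
#'
#' @param geno a [snp_genotypes()] matrix.
#' @param panel a [reference_panel()].
#' @return The genotype matrix with columns in panel order.
#' @export
align_genotypes <- function(geno, panel) {
  stopifnot(inherits(panel, "reference_panel"))
  idx <- match(panel$snp_ids, colnames(geno))
  if (anyNA(idx))
    stop("genotypes lack panel SNP(s): ",
         paste(utils::head(panel$snp_ids[is.na(idx)], 5L), collapse = ", "),
         call. = FALSE)
  geno[, idx, drop = FALSE]
}

#' Estimate a reference panel from labeled genotypes
#'
#' Computes per-breed allele-A frequencies from reference genotypes:
#' `freq[k, j]` is the count of A alleles among non-missing calls of breed
#' j at SNP k divided by twice the number of non-missing animals.
#' Genotype-class relative frequencies are computed from observed class
#' counts with additive (pseudocount) smoothing, so that curation
#' likelihoods are finite for classes unseen in the reference. Frequencies
#' are clamped to `[clamp, 1 - clamp]`.
#'
#' @param geno a [snp_genotypes()] matrix of reference animals.
#' @param breed breed label per animal; defaults to the genotypes' `breed`
#'   attribute.
#' @param pseudocount additive smoothing for genotype-class counts
#'   (default 0.5).
#' @param clamp frequency clamp (default 1e-6).
#' @param alleles optional allele annotation passed to [reference_panel()].
#' @return A `"reference_panel"` whose breed order follows the order of
#'   first appearance in `breed`.
#' @examples
#' g <- snp_genotypes(rbind(c(2, 1), c(1, 0)), breed = c("X", "X"))
#' allele_freq_panel(g)$freq  # A-allele frequencies 0.75 and 0.25
#' @export
allele_freq_panel <- function(geno, breed = NULL, pseudocount = 0.5,
                              clamp = 1e-6, alleles = NULL) {
  breed <- geno_breed(geno, breed)
  stopifnot(pseudocount >= 0)
  breeds <- unique(breed)
  M <- ncol(geno)
  freq <- matrix(NA_real_, M, length(breeds),
                 dimnames = list(colnames(geno), breeds))
  cls <- array(NA_real_, c(M, length(breeds), 3L))
  nan <- integer(length(breeds))
  g <- unclass(geno)
  for (j in seq_along(breeds)) {
    rows <- which(breed == breeds[j])
    if (!length(rows))
      stop("empty breed group: ", breeds[j], call. = FALSE)
    gj <- g[rows, , drop = FALSE]
    nobs <- colSums(!is.na(gj))
    if (any(nobs == 0L))
      stop(sprintf("SNP %s has no non-missing calls in breed %s",
                   colnames(geno)[which(nobs == 0L)[1L]], breeds[j]),
           call. = FALSE)
    freq[, j] <- colSums(gj, na.rm = TRUE) / (2 * nobs)
    n0 <- colSums(gj == 0L, na.rm = TRUE)
    n1 <- colSums(gj == 1L, na.rm = TRUE)
    n2 <- colSums(gj == 2L, na.rm = TRUE)
    tot <- nobs + 3 * pseudocount
    cls[, j, 1L] <- (n0 + pseudocount) / tot
    cls[, j, 2L] <- (n1 + pseudocount) / tot
    cls[, j, 3L] <- (n2 + pseudocount) / tot
    nan[j] <- length(rows)
  }
  names(nan) <- breeds
  reference_panel(freq, class_freq = cls, n_animals = nan,
                  alleles = alleles, clamp = clamp)
}

#' Likelihood-based breed membership score
#'
#' Scores how well an animal's genotypes fit a labeled breed's reference
#' distribution: the score is \eqn{(-2)\log} likelihood of the animal's
#' non-missing genotypes under the breed's per-SNP genotype distribution,
#' assuming independent SNPs. In `"multinomial"` mode the distribution is
#' the breed's observed genotype-class frequencies; in `"hwe"` mode it is
#' the Hardy-Weinberg distribution built from the breed's allele
#' frequency. With `normalization = "per_snp_mean"` (the default) the score
#' is divided by the number of non-missing SNPs, which puts the default
#' exclusion cutoff of 2 on a per-SNP scale; `"total"` returns the raw sum,
#' which is additive over disjoint SNP subsets.
#'
#' @param geno a [snp_genotypes()] matrix (one or more animals).
#' @param panel a [reference_panel()] with genotype-class frequencies
#'   (required for `"multinomial"` mode).
#' @param breed single breed label, or one label per animal.
#' @param mode `"multinomial"` (default) or `"hwe"`.
#' @param normalization `"per_snp_mean"` (default) or `"total"`.
#' @return Named numeric vector of nonnegative scores, one per animal.
#' @examples
#' pan <- reference_panel(matrix(0.5, 1, 1, dimnames = list("s1", "B")))
#' g <- snp_genotypes(matrix(1, 1, 1, dimnames = list("a1", "s1")))
#' membership_score(g, pan, "B", mode = "hwe")  # -2*log(0.5) = 1.386...
#' @export
membership_score <- function(geno, panel, breed,
                             mode = c("multinomial", "hwe"),
                             normalization = c("per_snp_mean", "total")) {
  mode <- match.arg(mode)
  normalization <- match.arg(normalization)
  stopifnot(inherits(panel, "reference_panel"))
  geno <- align_genotypes(geno, panel)
  n <- nrow(geno)
  if (length(breed) == 1L) breed <- rep(breed, n)
  if (length(breed) != n)
    stop("'breed' must be a single label or one per animal", call. = FALSE)
  bad <- setdiff(unique(breed), panel$breeds)
  if (length(bad))
    stop("unknown breed label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  if (mode == "multinomial" && is.null(panel$class_freq))
    stop("panel has no genotype-class frequencies; use mode = \"hwe\" or ",
         "build the panel with allele_freq_panel()", call. = FALSE)
  g <- unclass(geno)
  out <- numeric(n)
  for (i in seq_len(n)) {
    j <- match(breed[i], panel$breeds)
    gi <- g[i, ]
    obs <- !is.na(gi)
    if (!any(obs))
      stop("all genotypes missing for animal ", rownames(geno)[i],
           call. = FALSE)
    gi <- gi[obs]
    if (mode == "multinomial") {
      p <- panel$class_freq[obs, j, , drop = FALSE]
      dim(p) <- c(sum(obs), 3L)
      pr <- p[cbind(seq_along(gi), gi + 1L)]
    } else {
      q <- panel$freq[obs, j]
      pr <- ifelse(gi == 2L, q^2, ifelse(gi == 1L, 2 * q * (1 - q),
                                         (1 - q)^2))
    }
    s <- -2 * sum(log(pr))
    out[i] <- if (normalization == "per_snp_mean") s / length(gi) else s
  }
  names(out) <- rownames(geno)
  out
}

#' Curate a reference population by likelihood screening
#'
#' Removes putative outliers (e.g. mislabeled or crossbred animals) from
#' each breed's reference group: an animal is excluded when its
#' [membership_score()] against its own labeled breed exceeds `cutoff`.
#' The panel is first estimated from all animals, animals are screened
#' against it, and the panel is then re-estimated from the retained
#' animals. The procedure is deterministic given its inputs.
#'
#' @param geno a [snp_genotypes()] matrix of reference animals.
#' @param breed breed label per animal; defaults to the `breed` attribute.
#' @param cutoff positive exclusion threshold on the score (default 2).
#' @param mode,normalization passed to [membership_score()].
#' @param pseudocount,clamp passed to [allele_freq_panel()].
#' @param panel optional frozen [reference_panel()]: when supplied, scores
#'   are computed against it and no panel re-estimation takes place (a
#'   second screening pass against a frozen panel removes nothing new).
#' @return A list with elements `genotypes` (retained animals), `panel`
#'   (re-estimated from retained animals, or the frozen panel), and
#'   `report` (data frame: `animal_id`, `breed`, `score`, `excluded`).
#' @export
curate_reference <- function(geno, breed = NULL, cutoff = 2,
                             mode = c("multinomial", "hwe"),
                             normalization = c("per_snp_mean", "total"),
                             pseudocount = 0.5, clamp = 1e-6,
                             panel = NULL) {
  breed <- geno_breed(geno, breed)
  mode <- match.arg(mode)
  normalization <- match.arg(normalization)
  if (!is.numeric(cutoff) || length(cutoff) != 1L || is.na(cutoff) ||
      cutoff <= 0)
    stop("'cutoff' must be a single positive number", call. = FALSE)
  frozen <- !is.null(panel)
  if (!frozen)
    panel <- allele_freq_panel(geno, breed, pseudocount = pseudocount,
                               clamp = clamp)
  scores <- membership_score(geno, panel, breed, mode = mode,
                             normalization = normalization)
  excluded <- scores > cutoff
  report <- data.frame(animal_id = rownames(geno), breed = breed,
                       score = unname(scores), excluded = unname(excluded),
                       stringsAsFactors = FALSE)
  lost <- setdiff(unique(breed), unique(breed[!excluded]))
  if (length(lost))
    stop("all reference animals of breed ", paste(lost, collapse = ", "),
         " excluded at cutoff ", cutoff, "; use a larger cutoff",
         call. = FALSE)
  keep <- which(!excluded)
  retained <- geno[keep, , drop = FALSE]
  attr(retained, "breed") <- breed[keep]
  out_panel <- if (frozen) panel else
    allele_freq_panel(retained, breed[keep], pseudocount = pseudocount,
                      clamp = clamp)
  list(genotypes = retained, panel = out_panel, report = report)
}
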