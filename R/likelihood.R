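#' Hardy-Weinberg genotype probability
#'
#' Probability of a genotype code given the (possibly admixture-weighted)
#' frequency `f` of allele A, under Hardy-Weinberg equilibrium:
#' \eqn{f^2} for code 2 (AA), \eqn{2f(1-f)} for code 1 (AB), and
#' \eqn{(1-f)^2} for code 0 (BB). For any fixed `f` the three probabilities
#' sum to 1.
#'
#' @param g genotype code(s) in \{0, 1, 2\}.
#' @param f allele-A frequency in (0, 1); recycled against `g`.
#' @return numeric vector of probabilities.
#' @examples
#' genotype_probability(1, 0.5)  # 0.5
#' genotype_probability(2, 0.6)  # 0.36
#' @export
genotype_probability <- function(g, f) {
  if (any(is.na(g)) || !all(g %in% c(0, 1, 2)))
    stop("genotype codes must be 0, 1 or 2", call. = FALSE)
  if (any(!is.finite(f)) || any(f <= 0) || any(f >= 1))
    stop("'f' must lie strictly inside (0, 1)", call. = FALSE)
  ifelse(g == 2, f^2, ifelse(g == 1, 2 * f * (1 - f), (1 - f)^2))
}

## Extract the non-missing loci of one animal together with the matching
## rows of the panel's frequency matrix. Every likelihood-side routine
## funnels through this so missing-data handling lives in one place.
obs_data <- function(g, panel) {
  stopifnot(inherits(panel, "reference_panel"))
  g <- as.numeric(g)
  if (length(g) != length(panel$snp_ids))
    stop("genotype vector length does not match the panel's SNP count",
         call. = FALSE)
  obs <- !is.na(g)
  if (!any(obs)) stop("all genotype calls are missing", call. = FALSE)
  list(g = g[obs], q = panel$freq[obs, , drop = FALSE], n = sum(obs))
}

check_raw_x <- function(x, L) {
  x <- as.numeric(x)
  if (length(x) != L)
    stop("coefficient vector length does not match the panel's breed count",
         call. = FALSE)
  if (any(!is.finite(x)) || any(x < 0))
    stop("admixture coefficients must be finite and nonnegative",
         call. = FALSE)
  if (sum(x) <= 0)
    stop("admixture coefficients must not be all zero", call. = FALSE)
  x
}

## Core log-likelihood on pre-extracted data; scale-invariant in x.
ll_core <- function(g, q, x) {
  f <- drop(q %*% x) / sum(x)
  sum(g * log(f) + (2 - g) * log1p(-f))
}

## Core gradient in unnormalized coordinates (Euler-homogeneous of
## degree -1): d/dx_j of sum_k [g_k ln f_k + (2-g_k) ln(S-f_k)] - 2n ln S
## with f_k = sum_j q_jk x_j.
grad_core <- function(g, q, x) {
  S <- sum(x)
  f <- drop(q %*% x)
  drop(crossprod(q, g / f) + crossprod(1 - q, (2 - g) / (S - f))) - 2 * length(g) / S
}

## Diagonal of the Hessian of the same scale-invariant log-likelihood;
## negative of it is used as a curvature preconditioner.
hess_diag_core <- function(g, q, x) {
  S <- sum(x)
  f <- drop(q %*% x)
  drop(-crossprod(q^2, g / f^2) - crossprod((1 - q)^2, (2 - g) / (S - f)^2)) +
    2 * length(g) / S^2
}

## Full L x L Hessian; cheap for the small breed counts this model sees,
## and used for the tangent-space Newton polish near a solution.
hess_full_core <- function(g, q, x) {
  S <- sum(x)
  f <- drop(q %*% x)
  -crossprod(q * sqrt(g) / f, q * sqrt(g) / f) -
    crossprod((1 - q) * sqrt(2 - g) / (S - f), (1 - q) * sqrt(2 - g) / (S - f)) +
    2 * length(g) / S^2
}

#' Admixture model log-likelihood
#'
#' Log-likelihood of one animal's genotypes under the supervised admixture
#' model: with admixture coefficients \eqn{x_j \ge 0} and breed allele
#' frequencies \eqn{q_{jk}}, the animal's allele-A frequency at SNP k is
#' the mixture \eqn{\tilde f_k = \sum_j q_{jk} x_j / S(X)} with
#' \eqn{S(X) = \sum_j x_j}, and (HWE, independent loci)
#' \deqn{L(X) = \sum_k [\, g_k \ln \tilde f_k + (2-g_k) \ln(1-\tilde f_k)\,] + C,}
#' where the sum runs over the animal's non-missing loci and
#' \eqn{C = \sum_k \ln \binom{2}{g_k}} is constant in X. The function is
#' invariant to positive rescaling of `x`; only the direction of `x`
#' (equivalently, the breed composition `x / S(X)`) matters.
#'
#' @param g numeric genotype vector aligned to the panel's SNPs (codes
#'   0/1/2, `NA` for missing).
#' @param panel a [reference_panel()].
#' @param x nonnegative coefficient vector, one entry per panel breed, not
#'   all zero.
#' @param constant if `TRUE`, include the combinatorial constant C (so the
#'   value is an absolute log-probability); by default C is omitted, as it
#'   plays no role in estimation.
#' @return A single numeric value.
#' @examples
#' pan <- reference_panel(cbind(b1 = c(0.8, 0.2), b2 = c(0.4, 0.6)))
#' admix_loglik(c(2, 0), pan, c(0.5, 0.5))  # 4 * log(0.6)
#' @export
admix_loglik <- function(g, panel, x, constant = FALSE) {
  d <- obs_data(g, panel)
  x <- check_raw_x(x, ncol(panel$freq))
  ll <- ll_core(d$g, d$q, x)
  if (constant) ll <- ll + sum(log(choose(2, d$g)))
  ll
}

#' Gradient of the admixture log-likelihood
#'
#' Gradient of [admix_loglik()] with respect to the unnormalized
#' coefficients: component j is
#' \deqn{\nabla_j L = \sum_k \left[ \frac{g_k q_{jk}}{f_k} +
#'   \frac{(2-g_k)(1-q_{jk})}{S(X)-f_k} \right] - \frac{2n}{S(X)},}
#' with \eqn{f_k = \sum_j q_{jk} x_j} (unnormalized) and n the number of
#' non-missing loci. Because the log-likelihood is homogeneous of degree 0,
#' the gradient satisfies the Euler identity \eqn{\sum_j x_j \nabla_j L = 0}.
#'
#' @inheritParams admix_loglik
#' @return Numeric vector of length L (one component per breed).
#' @export
admix_gradient <- function(g, panel, x) {
  d <- obs_data(g, panel)
  x <- check_raw_x(x, ncol(panel$freq))
  grad_core(d$g, d$q, x)
}
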