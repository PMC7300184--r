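---
title: "Sparsely regularized admixture models for genomic breed composition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sparsely regularized admixture models for genomic breed composition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sparsemix)
```

## The model

A test animal is genotyped at $M$ biallelic SNPs, coded $g_k \in \{0, 1, 2\}$
as the number of copies of allele A. A reference panel supplies, for each of
$L$ breeds, the allele-A frequency $q_{jk}$ of breed $j$ at SNP $k$,
estimated beforehand from putatively purebred reference animals. The
supervised admixture model states that the animal's genome is a mixture of
the reference breeds with nonnegative weights $x_j$, so that its allele-A
frequency at SNP $k$ is $f_k = \sum_j q_{jk} x_j / S(X)$ with
$S(X)=\sum_j x_j$, and, assuming Hardy–Weinberg equilibrium and independent
loci,

$$L(X) = \sum_{k} \big[ g_k \ln f_k + (2-g_k)\ln(1-f_k) \big] + C,$$

with $C$ constant in $X$. The genomic breed composition (GBC) is the
normalized vector $x_j / S(X)$, which is nonnegative and sums to one.

The maximum-likelihood estimator has a well-known failure mode for purebred
identification: reference breeds that are genomically similar to the
animal's true breed attract small positive components, so a purebred animal
rarely receives GBC exactly 1 for its own breed. This is structural, not a
small-sample accident: at a purebred vertex the *expected* likelihood
gradient toward any other breed is exactly zero under the model, so the
fitted estimate falls on the wrong side of the vertex for a sizable share
of animals no matter how many SNPs are typed. `sparsemix` therefore fits
the penalized objective

$$F(X) = L(X) - \sum_j r_\lambda(|x_j|),$$

with three penalty families: L1 ($r_\lambda(x)=\lambda x$), the minimax
concave penalty (MCP) and the smoothly clipped absolute deviation (SCAD).
MCP and SCAD are linear with slope $\lambda$ near zero — suppressing small
non-essential components exactly as L1 does — but flatten to a constant for
$x \ge \lambda\gamma$, so a large genuine component is not shrunk. All
three make GBC $=1$ calls attainable exactly.

## Parameters that matter

* `lambda` ($\lambda \ge 0$, unitless): regularization strength. Defaults
  are 0.1 for L1 and 0.25 for MCP/SCAD, the values selected by three-fold
  cross-validation on the percent-pure criterion in large cattle panels;
  `cv_lambda()` re-selects them for any data set over a grid that defaults
  to $\{0, 0.05, \dots, 0.6\}$, covering the reported optima and bounds.
  Ties are broken toward the larger (sparser) $\lambda$.
* `gamma` ($\gamma > 1$): concavity of MCP/SCAD; larger is less concave.
  The default 3 is the conventional choice and the one used for the
  published cattle analyses.
* `cutoff` (curation, default 2): reference animals whose per-SNP mean
  $(-2)\log$-likelihood under their own breed's genotype-class
  distribution exceeds the cutoff are excluded as outliers. The per-SNP
  mean scale is the only one on which a fixed default of 2 is operable —
  a raw sum over thousands of SNPs exceeds 2 for every animal — so that is
  the default `normalization`; the raw-sum mode is also exposed. Curation
  defaults to the multinomial (observed genotype-class) likelihood with
  pseudocount 0.5; an HWE-based alternative is available because the
  admixture model itself assumes HWE.
* Solver options (`admix_control()`): KKT tolerance `tol_kkt = 1e-4`
  defines convergence; `zero_clip = 1e-8` sets components below it to
  exactly 0 before the final normalization, so "GBC = 1" is an exact
  category, matching its use as a reporting boundary.

## The optimizer

The likelihood is invariant to positive rescaling of $X$ (it is
homogeneous of degree zero), and its printed gradient,

$$\nabla_j L = \sum_k \left[ \frac{g_k q_{jk}}{f_k} +
\frac{(2-g_k)(1-q_{jk})}{S(X)-f_k} \right] - \frac{2n}{S(X)},$$

satisfies the Euler identity $\sum_j x_j \nabla_j L = 0$. The optimizer
therefore works in nonnegative coordinates, renormalizing each accepted
iterate onto the simplex (which costs nothing in $L$ and fixes the scale
at which the penalty acts), and treats the non-differentiability of
$r_\lambda(|x_j|)$ at $0$ with a minimum-norm subgradient rule: a
coordinate sitting at exactly zero has search direction zero — is
*absorbed* — unless its likelihood gradient exceeds the active
coordinates' common gradient level $\mu$ by more than the subdifferential
bound $d_0 = \lambda$. This absorption is the mechanism by which larger
$\lambda$ yields sparser solutions and exact purebred calls: at a vertex,
a penalized family tolerates spurious gradients up to $\lambda$ where the
unpenalized model tolerates none.

Active coordinates move along the penalized gradient
$\nabla_j L - r'_\lambda(x_j)$, diagonally preconditioned by the
per-coordinate curvature, with Armijo backtracking (factor 0.5,
$c_1 = 10^{-4}$) and projection onto the nonnegative orthant. Because
breed frequency columns are correlated (they share an ancestral
frequency), the diagonal preconditioner alone creeps near the solution;
once the active set has been stable for two accepted steps the solver
switches to an equality-constrained Newton step on the active face using
the full $L \times L$ Hessian, which is cheap at the breed counts this
model sees and converges quadratically. Every step must increase $F$, so
the accepted sequence is monotone.

Convergence is certified, not assumed: a point is declared converged only
when an independently coded first-order checker (`admix_kkt()`) finds a
multiplier $\mu$ with $\nabla_j L - r'_\lambda(x_j) = \mu$ (within
`tol_kkt`) on the active set and $\nabla_j L - d_0 \le \mu$ on the zero
set. With $\lambda = 0$ the fit reproduces the maximum-likelihood
estimate; an EM solver with the classical multiplicative update
(`admix_em()`), whose iterates stay on the simplex exactly and ascend the
likelihood monotonically, serves as an independent oracle for that case
and agrees with the optimizer to $10^{-6}$ per component in the test
suite. For $L = 2$ every penalized fit is also checked against an
exhaustive grid search of $F$ over the simplex.

MCP and SCAD are non-convex, so local optima exist. `init = "multistart"`
runs the solver from the uniform start and every vertex and keeps the
best objective, breaking ties toward the smaller penalty and then breed
order; the default single uniform start reproduces the behaviour of a
practitioner running one fit and is what the cross-validated defaults
were tuned under.

## Composite animals

For a composite breed with declared ancestors (Brangus-type animals are
stabilized at 5/8 Angus, 3/8 Brahman), two estimators are provided.
`conditional_gbc()` renormalizes the full-panel GBC over the declared
ancestral subset — the composition conditional on ancestry lying in the
subset — and always sums to one per animal. Summaries of conditional
results average *per-animal ratios*; the alternative ratio-of-means
convention is inconsistent with how bracketed conditional means are
conventionally reported, and the two differ (the package's worked example
gives 75.0 vs 73.7 on a two-animal case), so the convention is fixed and
documented. `admix_fit_restricted()` instead refits against a panel
containing only the ancestral breeds. The two agree exactly whenever the
full fit already places zero mass outside the subset.

Regularization and composites interact with a caution: penalties attract
estimates toward vertices, which is desirable for purebreds but biases
composite estimates toward the major ancestral breed. The test suite
checks the direction of this effect (the MCP estimate of the major
component is never below the ML estimate on the same data) and the
package's defaults leave $\lambda$ configurable for composite work; the
unpenalized fit is the safe reference point there.

## What the simulator emulates — and what it does not

`simulate_panel()` draws breed allele frequencies under the
Balding–Nichols model: ancestral frequencies $p_k$ uniform on
$[0.1, 0.9]$, breed frequencies Beta-distributed with mean $p_k$ and
variance $F_{ST}\,p_k(1-p_k)$. Defaults use $F_{ST}$ in the 0.05–0.15
range, matching the moderate divergence of cattle breeds
($F_{ST} < 0.10$ for the taurine breeds). `simulate_genotypes()` draws
HWE genotypes Binomial$(2, f_k)$ at the admixture-weighted frequency;
drawing each allele copy independently by breed of origin is equivalent
under the model's own assumptions, so no pedigree or recombination
machinery is included. Fixtures are deterministic given a seed.

The simulator deliberately omits linkage disequilibrium, genotyping
error, ascertainment bias of SNP chips, and within-breed structure. The
model itself assumes independent loci, so the simulation matches the
model exactly; passing tests therefore demonstrate correctness of the
estimator under its own assumptions, not robustness to their violation.
In real chip data LD makes likelihoods overconfident, and the power of
purebred identification degrades as panels grow denser — one reason
regularized fits are valuable there. Conversely, the *gap* between
penalized and unpenalized percent-pure is much smaller in these LD-free
simulations (a fraction of a percentage point at $F_{ST}=0.05$,
$M = 5000$) than in real cattle data, where between-breed similarity is
structured rather than independent across loci: the simulations verify
the ordering of the methods, not the magnitude of the real-data gains.

## Numerical choices and degenerate inputs

* Frequencies are clamped to $[\epsilon_f, 1-\epsilon_f]$ with
  $\epsilon_f = 10^{-6}$ at panel construction, so monomorphic reference
  SNPs cannot produce infinite log terms.
* Missing genotypes are dropped from the affected animal's likelihood
  (the per-animal SNP count $n$ adjusts); an all-missing animal is an
  error.
* A one-breed panel returns GBC $= 1$ without optimization; an all-zero
  coefficient vector is rejected.
* Exact zeros arise from projection during optimization and from the
  final `zero_clip`; the reported vector is renormalized afterwards, so
  rows sum to 1 at machine precision and pure calls are exact.
* Writers emit fixed six-decimal formatting (exact 0 and 1 as bare
  digits), fixed column order, and `\n` line endings, so identical runs
  give byte-identical files.

## Problem sizes used in the checks

The test suite and the acceptance script size their simulations to run
comfortably on a laptop while keeping every estimate well-identified:
oracle comparisons use $L \le 5$, $M \le 200$ over dozens of random
instances; parameter-recovery and screening designs use $M$ = 1000–2000
with 50–220 animals; and the purebred power comparison uses the full
five-breed, $M = 5000$, 200-animals-per-breed design at $F_{ST} = 0.05$.
These sizes were chosen so that binomial sampling error is far below the
tolerances being asserted (e.g. the standard error of a mean GBC over 200
animals at $M = 2000$ is about 0.002 against a bias tolerance of 0.02).

## Known limitations

* Reference allele frequencies are treated as known constants; their
  sampling error propagates into GBC without being reflected in any
  reported uncertainty (visible in cross-validation, where fold-estimated
  focal frequencies sharply reduce percent-pure relative to full-panel
  frequencies).
* No LD modelling; dense panels violate the independence assumption in
  real data.
* Non-convexity means the returned MCP/SCAD fit is a certified
  stationary point, not a guaranteed global optimum; multistart mitigates
  but does not remove this.
* The curation screen assumes the majority of each reference group is
  correctly labeled; a heavily contaminated group shifts its own
  genotype-class frequencies and can mask outliers.
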