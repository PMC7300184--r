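#' Solver options for the admixture optimizer
#'
#' @param max_iter maximum outer iterations per animal (default 500).
#' @param tol_obj relative objective-change tolerance used as a stall
#'   detector (default 1e-9).
#' @param tol_kkt tolerance on the first-order (KKT) residual that defines
#'   convergence (default 1e-4).
#' @param zero_clip components with raw value below this are set to exactly
#'   0 before the final normalization, so purebred calls (GBC = 1) are
#'   exact (default 1e-8).
#' @param armijo_c1 sufficient-increase constant of the backtracking line
#'   search (default 1e-4).
#' @param step_shrink backtracking contraction factor (default 0.5).
#' @param max_backtrack maximum step halvings per iteration (default 50).
#' @return A list of class `"admix_control"`.
#' @export
admix_control <- function(max_iter = 500L, tol_obj = 1e-9, tol_kkt = 1e-4,
                          zero_clip = 1e-8, armijo_c1 = 1e-4,
                          step_shrink = 0.5, max_backtrack = 50L) {
  stopifnot(max_iter >= 1L, tol_obj > 0, tol_kkt > 0, zero_clip > 0,
            armijo_c1 > 0, armijo_c1 < 1, step_shrink > 0, step_shrink < 1,
            max_backtrack >= 1L)
  structure(list(max_iter = as.integer(max_iter), tol_obj = tol_obj,
                 tol_kkt = tol_kkt, zero_clip = zero_clip,
                 armijo_c1 = armijo_c1, step_shrink = step_shrink,
                 max_backtrack = as.integer(max_backtrack)),
            class = "admix_control")
}

## Penalized objective F(X) = L(X) - sum_j r_lambda(x_j), evaluated on the
## simplex (x normalized).
obj_core <- function(g, q, x, spec) {
  ll_core(g, q, x) - sum(penalty_value(x / sum(x), spec))
}

## KKT residual of max F over the simplex at x (on the simplex):
## there must exist mu with  grad_j L - r'(x_j) = mu  for x_j > 0 and
## grad_j L - d0 <= mu  for x_j = 0.  Returns the residual and mu.
kkt_core <- function(g, q, x, spec) {
  act <- x > 0
  G <- grad_core(g, q, x)
  psi <- G - penalty_deriv(x, spec)
  mu <- sum(x[act] * psi[act]) / sum(x[act])
  res <- max(abs(psi[act] - mu))
  if (any(!act)) {
    d0 <- penalty_d0(spec)
    res <- max(res, max(G[!act] - d0 - mu, 0))
  }
  list(residual = res, mu = mu, grad = G, psi = psi)
}

## One-animal fit by projected, diagonally preconditioned minimum-norm
## subgradient ascent. x is kept on the simplex: the likelihood is
## scale-invariant, so renormalizing after each projected step costs
## nothing in L while fixing the scale at which the penalty acts.
## Coordinates at exactly 0 are absorbed by the subdifferential of the
## penalty unless their likelihood gradient exceeds the active
## coordinates' common level mu by more than d0.
fit_one <- function(g, q, spec, control, x0) {
  L <- ncol(q)
  if (L == 1L) {
    return(list(raw = 1, gbc = 1, loglik = ll_core(g, q, 1),
                n_iter = 0L, converged = TRUE, kkt = 0))
  }
  d0 <- penalty_d0(spec)
  x <- x0 / sum(x0)
  Fx <- obj_core(g, q, x, spec)
  iter <- 0L
  converged <- FALSE
  kkt_val <- Inf
  stall <- 0L
  act_prev <- rep(TRUE, L)
  act_stable <- 0L
  repeat {
    kk <- kkt_core(g, q, x, spec)
    kkt_val <- kk$residual
    if (kkt_val <= control$tol_kkt) { converged <- TRUE; break }
    if (iter >= control$max_iter || stall >= 5L) break
    iter <- iter + 1L

    act <- x > 0
    act_stable <- if (identical(act, act_prev)) act_stable + 1L else 0L
    act_prev <- act
    d <- numeric(L)
    d[act] <- kk$psi[act]
    rel <- !act & (kk$grad - d0 - kk$mu > 0)
    d[rel] <- (kk$grad - d0 - kk$mu)[rel]

    H <- hess_diag_core(g, q, x)
    h <- pmax(-H, 1e-6 * max(-H, 1))
    rp <- penalty_deriv(x, spec)
    dir_slope <- function(p)
      sum((kk$grad - rp) * p) + sum(p) * sum(x * rp)

    ## Endgame polish: once the minimum-norm subgradient phase has
    ## settled the active set, switch to a tangent-space Newton step on
    ## it (full Hessian of the penalized objective, equality-constrained
    ## to sum(step) = 0). The breed frequency columns are correlated, so
    ## the diagonal preconditioner alone creeps near the solution while
    ## this converges quadratically. Guarded: used only when the solve
    ## succeeds and the step is an ascent direction.
    p <- NULL
    ka <- sum(act)
    if (ka >= 2L && !any(rel) && act_stable >= 2L) {
      Hf <- hess_full_core(g, q, x)[act, act, drop = FALSE] -
        diag(penalty_deriv2(x[act], spec), ka)
      sys <- cbind(rbind(Hf, 1), c(rep(1, ka), 0))
      sol <- tryCatch(solve(sys, c(-kk$psi[act], 0)), error = function(e) NULL)
      if (!is.null(sol) && all(is.finite(sol))) {
        pn <- numeric(L)
        pn[act] <- sol[seq_len(ka)]
        if (dir_slope(pn) > 0) p <- pn
      }
    }
    if (is.null(p)) p <- d / h
    slope <- dir_slope(p)
    if (slope <= 0) {
      ## fall back to the tangent-projected first-order direction
      d[act] <- kk$psi[act] - kk$mu
      p <- d / h
      slope <- dir_slope(p)
      if (slope <= 0) break
    }

    t <- 1
    accepted <- FALSE
    for (bt in seq_len(control$max_backtrack)) {
      y <- pmax(x + t * p, 0)
      sy <- sum(y)
      if (sy > 0) {
        y <- y / sy
        Fy <- obj_core(g, q, y, spec)
        if (Fy >= Fx + control$armijo_c1 * t * slope) {
          ## count consecutive accepted steps that move neither the
          ## objective (at machine precision) nor the active set: a run
          ## of them means the iteration has hit its numerical floor
          stall <- if (Fy == Fx && identical(y > 0, x > 0))
            stall + 1L else 0L
          x <- y
          Fx <- Fy
          accepted <- TRUE
          break
        }
      }
      t <- t * control$step_shrink
    }
    if (!accepted) break
  }
  if (!converged) {
    kkt_val <- kkt_core(g, q, x, spec)$residual
    converged <- kkt_val <= control$tol_kkt
  }
  ## exact-zero clip so purebred calls are exact, then final normalization
  x[x < control$zero_clip] <- 0
  x <- x / sum(x)
  list(raw = x, gbc = x, loglik = ll_core(g, q, x), n_iter = iter,
       converged = converged, kkt = kkt_val)
}

fit_one_multistart <- function(g, q, spec, control) {
  L <- ncol(q)
  starts <- c(list(rep(1 / L, L)),
              lapply(seq_len(L), function(j) {
                e <- rep(0, L); e[j] <- 1; e
              }))
  fits <- lapply(starts, function(s) fit_one(g, q, spec, control, s))
  Fv <- vapply(fits, function(f)
    f$loglik - sum(penalty_value(f$gbc, spec)), numeric(1))
  best <- which(Fv >= max(Fv) - 1e-9)
  if (length(best) > 1L) {
    pen <- vapply(fits[best], function(f) sum(penalty_value(f$gbc, spec)),
                  numeric(1))
    best <- best[pen <= min(pen) + 1e-12]
  }
  fits[[best[1L]]]
}

#' Fit sparsely regularized admixture models
#'
#' Estimates the genomic breed composition (GBC) of each animal by
#' maximizing the penalized admixture log-likelihood
#' \deqn{F(X) = L(X) - \sum_j r_\lambda(|x_j|)}
#' over nonnegative coefficients, where \eqn{L(X)} is the scale-invariant
#' admixture log-likelihood ([admix_loglik()]) and \eqn{r_\lambda} is the
#' chosen penalty ([penalty_spec()]). The reported GBC is the normalized
#' coefficient vector \eqn{x_j / S(X)}, which is nonnegative and sums
#' to 1.
#'
#' The optimizer is a projected minimum-norm subgradient ascent with a
#' diagonal curvature preconditioner and Armijo backtracking. Coefficients
#' that reach exactly zero are held there as long as their likelihood
#' gradient lies within the penalty's subdifferential bound of the active
#' coefficients' common gradient level; this absorption is what produces
#' exact zeros — and exact GBC = 1 purebred calls — under the penalized
#' families. With `penalty = "none"` (or `lambda = 0`) the result is the
#' unpenalized maximum-likelihood estimate. Convergence is certified by a
#' first-order (KKT) residual; see [admix_kkt()].
#'
#' Non-convex penalties (MCP, SCAD) can have multiple local optima;
#' `init = "multistart"` runs the solver from the uniform start and from
#' every vertex of the simplex and keeps the best objective (ties broken
#' toward the smaller penalty, then breed order).
#'
#' @param geno a [snp_genotypes()] matrix (animals x SNPs), or a single
#'   genotype vector, aligned or alignable to `panel` by SNP id.
#' @param panel a [reference_panel()].
#' @param penalty a [penalty_spec()] or a family name (`"none"`, `"l1"`,
#'   `"mcp"`, `"scad"`).
#' @param lambda,gamma used when `penalty` is a family name; `lambda`
#'   defaults to the family's documented default (0.1 for L1, 0.25 for
#'   MCP/SCAD).
#' @param control an [admix_control()] list.
#' @param init `"uniform"` (default) or `"multistart"`, or a numeric
#'   vector of starting proportions.
#' @return An object of class `"admix_fit"` with components
#'   \describe{
#'     \item{gbc}{animals x breeds matrix of breed composition (rows sum
#'       to 1; entries of exactly 0 and 1 occur).}
#'     \item{loglik}{per-animal log-likelihood at the solution, including
#'       the combinatorial constant.}
#'     \item{n_iter, converged, kkt}{per-animal iteration count,
#'       convergence flag, and KKT residual.}
#'     \item{n_snps_used}{per-animal count of non-missing loci.}
#'     \item{penalty, control, breeds, panel}{the specification used.}
#'   }
#'   Methods: `print`, `summary`, `coef` (the GBC matrix), `logLik`,
#'   `plot`, `simulate`.
#' @examples
#' pan <- simulate_panel(n_breeds = 3, n_snps = 300, fst = 0.1, seed = 1)
#' g <- simulate_genotypes(pan, admixture = c(1, 0, 0), n_animals = 4,
#'                         seed = 2)
#' fit <- admix_fit(g, pan, penalty = "mcp")
#' coef(fit)
#' @export
admix_fit <- function(geno, panel, penalty = "none", lambda = NULL,
                      gamma = 3, control = admix_control(),
                      init = "uniform") {
  stopifnot(inherits(panel, "reference_panel"))
  spec <- as_penalty_spec(penalty, lambda, gamma)
  if (is.null(dim(geno))) {
    geno <- matrix(geno, nrow = 1L,
                   dimnames = list("animal_1", panel$snp_ids))
  }
  if (!is.null(colnames(geno))) geno <- align_genotypes(geno, panel)
  if (ncol(geno) != length(panel$snp_ids))
    stop("genotypes and panel have different SNP counts and the genotypes ",
         "carry no SNP ids to align by", call. = FALSE)
  n_animal <- nrow(geno)
  L <- length(panel$breeds)
  ids <- rownames(geno) %||% sprintf("animal_%d", seq_len(n_animal))
  multistart <- identical(init, "multistart")
  x0 <- if (is.numeric(init)) check_raw_x(init, L) else rep(1 / L, L)

  gbc <- matrix(NA_real_, n_animal, L, dimnames = list(ids, panel$breeds))
  loglik <- kkt <- numeric(n_animal)
  n_iter <- n_used <- integer(n_animal)
  converged <- logical(n_animal)
  gm <- unclass(geno)
  for (i in seq_len(n_animal)) {
    d <- obs_data(gm[i, ], panel)
    f <- if (multistart) fit_one_multistart(d$g, d$q, spec, control)
         else fit_one(d$g, d$q, spec, control, x0)
    gbc[i, ] <- f$gbc
    loglik[i] <- f$loglik + sum(log(choose(2, d$g)))
    n_iter[i] <- f$n_iter
    converged[i] <- f$converged
    kkt[i] <- f$kkt
    n_used[i] <- d$n
  }
  if (any(!converged))
    warning(sum(!converged), " animal(s) did not reach the KKT tolerance; ",
            "their 'converged' flag is FALSE", call. = FALSE)
  structure(list(gbc = gbc, loglik = loglik, n_iter = n_iter,
                 converged = converged, kkt = kkt, n_snps_used = n_used,
                 penalty = spec, control = control, breeds = panel$breeds,
                 panel = panel, animal_ids = ids),
            class = "admix_fit")
}

#' Independent KKT certificate for an admixture estimate
#'
#' Checks, from scratch, the first-order optimality conditions of
#' maximizing the penalized admixture objective over the probability
#' simplex at a proposed GBC vector: there must exist a multiplier
#' \eqn{\mu} with \eqn{\nabla_j L - r'_\lambda(x_j) = \mu} for every
#' active component and \eqn{\nabla_j L - d_0 \le \mu} for every zero
#' component, where \eqn{d_0} bounds the penalty subdifferential at 0.
#' The returned residual is the largest violation; a converged
#' [admix_fit()] estimate satisfies `residual <= control$tol_kkt`.
#'
#' @param gbc nonnegative GBC vector (sums to 1).
#' @param g genotype vector aligned to the panel.
#' @param panel a [reference_panel()].
#' @param penalty,lambda,gamma the penalty under which the estimate was
#'   produced (a [penalty_spec()] or family name).
#' @return For a vector: the scalar KKT residual. For
#'   `admix_kkt_fit()`: a numeric vector of residuals, one per animal.
#' @export
admix_kkt <- function(gbc, g, panel, penalty = "none",
                      lambda = NULL, gamma = 3) {
  spec <- as_penalty_spec(penalty, lambda, gamma)
  d <- obs_data(g, panel)
  x <- check_raw_x(gbc, ncol(panel$freq))
  if (length(x) > 1L) kkt_core(d$g, d$q, x, spec)$residual else 0
}

#' @rdname admix_kkt
#' @param fit an `"admix_fit"` object.
#' @param geno the genotype matrix the fit was produced from.
#' @export
admix_kkt_fit <- function(fit, geno) {
  stopifnot(inherits(fit, "admix_fit"))
  if (is.null(dim(geno))) geno <- matrix(geno, nrow = 1L)
  if (!is.null(colnames(geno))) geno <- align_genotypes(geno, fit$panel)
  vapply(seq_len(nrow(geno)), function(i)
    admix_kkt(fit$gbc[i, ], unclass(geno)[i, ], fit$panel, fit$penalty),
    numeric(1))
}

#' EM solver for the unpenalized admixture model
#'
#' Maximum-likelihood admixture proportions by the classical EM update
#' \deqn{x_j \leftarrow \frac{x_j}{2n} \sum_k \left[
#'   \frac{g_k q_{jk}}{f_k} + \frac{(2-g_k)(1-q_{jk})}{1-f_k} \right],}
#' with \eqn{f_k} computed from the simplex-normalized coefficients. The
#' update preserves \eqn{\sum_j x_j = 1} exactly and never decreases the
#' likelihood; its fixed points are the maximum-likelihood estimates.
#' Serves as an independent cross-check of [admix_fit()] at
#' \eqn{\lambda = 0}.
#'
#' @param g genotype vector aligned to the panel (codes 0/1/2, `NA`
#'   allowed).
#' @param panel a [reference_panel()].
#' @param max_iter,tol iteration cap and convergence tolerance on the
#'   largest coefficient change.
#' @param trace if `TRUE`, also return the log-likelihood after each
#'   iteration.
#' @return A list with `gbc`, `loglik`, `n_iter`, and (if traced)
#'   `loglik_path`.
#' @export
admix_em <- function(g, panel, max_iter = 10000L, tol = 1e-12,
                     trace = FALSE) {
  d <- obs_data(g, panel)
  L <- ncol(d$q)
  x <- rep(1 / L, L)
  n2 <- 2 * d$n
  path <- if (trace) numeric(0) else NULL
  it <- 0L
  repeat {
    it <- it + 1L
    xn <- x * (grad_core(d$g, d$q, x) + n2) / n2
    if (trace) path <- c(path, ll_core(d$g, d$q, xn))
    delta <- max(abs(xn - x))
    x <- xn
    if (delta < tol || it >= max_iter) break
  }
  names(x) <- colnames(d$q)
  out <- list(gbc = x, loglik = ll_core(d$g, d$q, x), n_iter = it)
  if (trace) out$loglik_path <- path
  out
}
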