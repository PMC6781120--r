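#' Control parameters for REML estimation
#'
#' @param tol_param Relative parameter-change tolerance declaring
#'   convergence (joint with `tol_grad`).
#' @param tol_grad Gradient-norm tolerance.
#' @param max_iter Maximum number of iterations.
#' @param verbose Print per-iteration log-likelihoods.
#' @return A list of control values.
#' @export
reml_control <- function(tol_param = 1e-8, tol_grad = 1e-6, max_iter = 50L,
                         verbose = FALSE) {
  list(tol_param = tol_param, tol_grad = tol_grad,
       max_iter = as.integer(max_iter), verbose = verbose)
}

## ---- internal helpers ------------------------------------------------------

## Selected inverse of C on its sparsity pattern, from a simplicial
## Cholesky factorization (Takahashi equations, compiled kernel).
selected_inverse <- function(C, ch = NULL) {
  ## the Takahashi recursion needs a simplicial factor (diagonal-first,
  ## sorted columns); refactor unless one was supplied
  if (is.null(ch) || !methods::is(ch, "dCHMsimpl"))
    ch <- mme_cholesky(C, super = FALSE)
  ex <- Matrix::expand(ch)
  L <- ex$L
  Sx <- .takahashi_inverse(L@p, L@i, L@x, nrow(L))
  Slow <- Matrix::sparseMatrix(i = L@i, p = L@p, x = Sx, dims = dim(L),
                               index1 = FALSE, triangular = FALSE)
  Ssym <- Matrix::forceSymmetric(Slow, uplo = "L")
  ## C = P' L L' P  =>  inv(C) = P' inv(LL') P
  S <- Matrix::crossprod(ex$P, Ssym) %*% ex$P
  list(S = Matrix::forceSymmetric(S), chol = ch,
       logdet = 2 * sum(log(Matrix::diag(L))))
}

## Sparse Cholesky of the MME coefficient matrix. Supernodal first (more
## robust under extreme variance ratios), simplicial fallback, then a tiny
## diagonal jitter as a last resort.
mme_cholesky <- function(C, super = TRUE) {
  f <- function(M) Matrix::Cholesky(M, perm = TRUE, super = super,
                                    LDL = FALSE)
  out <- tryCatch(f(C), error = function(e) NULL)
  if (!is.null(out)) return(out)
  ## escalating diagonal jitter, scaled to the typical (median) pivot so
  ## boundary-pinned blocks with huge entries do not inflate it
  scale <- stats::median(Matrix::diag(C))
  for (jit in scale * c(1e-10, 1e-8, 1e-6, 1e-4)) {
    out <- tryCatch(f(C + Matrix::Diagonal(nrow(C), jit)),
                    error = function(e) NULL)
    if (!is.null(out)) return(out)
  }
  stop("mixed-model coefficient matrix could not be factorized")
}

## tr(A %*% B) for sparse symmetric A and sparse B (summed over A's pattern)
trace_prod <- function(A, B) {
  sum(methods::as(A, "generalMatrix") * Matrix::t(methods::as(B, "generalMatrix")))
}

pack_params <- function(vc, terms) {
  th <- c()
  nm <- c()
  for (tm in terms) {
    cmp <- vc$components[[tm$name]]
    if (tm$slope) {
      th <- c(th, cmp[1, 1], cmp[1, 2], cmp[2, 2])
      nm <- c(nm, paste0(tm$name, c("_v0", "_c01", "_v1")))
    } else {
      th <- c(th, as.numeric(cmp))
      nm <- c(nm, tm$name)
    }
  }
  stats::setNames(c(th, vc$sigma2_e), c(nm, "sigma2_e"))
}

unpack_params <- function(th, terms) {
  comps <- list()
  k <- 1L
  for (tm in terms) {
    if (tm$slope) {
      comps[[tm$name]] <- matrix(c(th[k], th[k + 1], th[k + 1], th[k + 2]), 2, 2)
      k <- k + 3L
    } else {
      comps[[tm$name]] <- th[k]
      k <- k + 1L
    }
  }
  list(components = comps, sigma2_e = th[k])
}

## validity is judged in the internal (standardized-covariable) basis so
## that the boundary floor keeps the system's dynamic range bounded
params_valid <- function(th, terms, floor_v) {
  k <- 1L
  for (tm in terms) {
    if (tm$slope) {
      Tsc <- diag(c(1, tm$cv_scale))
      S <- Tsc %*% matrix(c(th[k], th[k + 1], th[k + 1], th[k + 2]),
                          2, 2) %*% Tsc
      ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
      if (min(ev) < floor_v) return(FALSE)
      k <- k + 3L
    } else {
      if (th[k] < floor_v) return(FALSE)
      k <- k + 1L
    }
  }
  th[k] >= floor_v
}

## indices of (v0, c01, v1) triplets in the packed parameter vector
slope_triplets <- function(terms) {
  out <- list(); k <- 1L
  for (tm in terms) {
    if (tm$slope) { out[[length(out) + 1L]] <- k:(k + 2L); k <- k + 3L }
    else k <- k + 1L
  }
  out
}

## d(theta_internal)/d(theta_raw) per packed parameter
param_scale <- function(terms) {
  ps <- c()
  for (tm in terms) {
    if (tm$slope) ps <- c(ps, 1, tm$cv_scale, tm$cv_scale^2)
    else ps <- c(ps, 1)
  }
  c(ps, 1)
}

## REML log-likelihood (and solutions) for given components; no traces.
reml_loglik <- function(design, vc) {
  prior <- mme_prior(design, vc)
  C <- Matrix::forceSymmetric(design$WtW / vc$sigma2_e + prior$Gstar)
  ch <- mme_cholesky(C)
  theta <- as.numeric(Matrix::solve(ch, design$Wty / vc$sigma2_e))
  yPy <- (design$yty - sum(theta * design$Wty)) / vc$sigma2_e
  ldC <- 2 * as.numeric(Matrix::determinant(ch, logarithm = TRUE, sqrt = TRUE)$modulus)
  logL <- -0.5 * (design$n * log(vc$sigma2_e) - design$sum_log_w +
                    prior$logdetG + ldC + yPy)
  list(logL = logL, theta = theta, yPy = yPy, C = C, prior = prior, chol = ch)
}

## ---- the estimator ---------------------------------------------------------

#' Estimate variance components by average information REML
#'
#' Maximises the restricted likelihood of the model in `spec` by average
#' information (AI) updates computed from working vectors, with exact first
#' derivatives obtained from a sparse selected inverse of the mixed-model
#' coefficient matrix (Takahashi equations). When an AI step leaves the
#' parameter space, or fails to improve the restricted likelihood, an
#' expectation-maximisation (EM) step is taken instead; EM steps never
#' decrease the likelihood. Variances shrinking to zero are pinned at
#' `1e-8` times the phenotypic variance and flagged as boundary estimates.
#'
#' @param spec An [rnm_model_spec()].
#' @param data Phenotype `data.frame`.
#' @param kinships Named list of `kinship` inverses for kinship terms.
#' @param init Optional starting values: list with `components` (named list
#'   of scalars / 2x2 matrices) and `sigma2_e`. A crude equal-split start is
#'   used when `NULL`.
#' @param control A [reml_control()].
#' @return An object of class `vc_fit`: variance `components`, residual
#'   `sigma2_e`, REML `logLik`, asymptotic `se` (from the inverse AI
#'   matrix), BLUE/BLUP `solutions`, `gradient`, convergence information and
#'   boundary flags.
#' @export
reml_estimate <- function(spec, data, kinships = list(), init = NULL,
                          control = reml_control()) {
  design <- mme_design(spec, data, kinships)
  vy <- stats::var(design$y)
  floor_v <- 1e-8 * vy
  if (is.null(init)) {
    nt <- length(design$terms)
    share <- vy / (nt + 1)
    comps <- list()
    for (tm in design$terms) {
      if (tm$slope) {
        vcv <- stats::var(data[[spec$covariable]])
        vslope <- if (is.finite(vcv) && vcv > 1e-12) share / vcv else share
        comps[[tm$name]] <- matrix(c(share, 0, 0, vslope), 2, 2)
      } else comps[[tm$name]] <- share
    }
    init <- list(components = comps, sigma2_e = share)
  }
  vc <- init
  th <- pack_params(vc, design$terms)
  n_par <- length(th)
  par_names <- names(th)
  pscale <- param_scale(design$terms)
  flo <- floor_v / pscale              # raw-basis floors per parameter
  cur <- reml_loglik(design, vc)
  boundary <- rep(FALSE, n_par)
  frozen <- rep(FALSE, n_par)            # pinned at the boundary floor
  var_par <- !grepl("_c01", par_names)   # covariances may cross zero freely
  converged <- FALSE
  AI <- NULL; grad <- NULL
  iter <- 0L
  step_type <- "none"
  rel_change <- Inf
  th_prev <- th

  for (iter in seq_len(control$max_iter)) {
    si <- selected_inverse(cur$C, cur$chol)
    S <- si$S
    theta <- cur$theta
    e <- design$y - as.numeric(design$W %*% theta)
    ee_w <- sum(design$w_rec * e^2)
    s2e <- vc$sigma2_e

    grad <- numeric(n_par)
    em <- numeric(n_par)
    work <- matrix(0, design$n, n_par)
    ps <- pscale
    trCG <- 0
    k <- 1L
    for (tm in design$terms) {
      cols <- tm$cols
      if (tm$slope) {
        U <- matrix(theta[cols], ncol = 2)
        KU <- as.matrix(tm$Kinv %*% U)
        B <- crossprod(U, KU)
        Tsc <- diag(c(1, tm$cv_scale))
        Sg <- Tsc %*% as.matrix(vc$components[[tm$name]]) %*% Tsc
        Sinv <- solve(Sg)
        q <- tm$q
        c0 <- cols[seq_len(q)]; c1 <- cols[q + seq_len(q)]
        Tm <- matrix(0, 2, 2)
        Tm[1, 1] <- trace_prod(tm$Kinv, S[c0, c0])
        Tm[2, 2] <- trace_prod(tm$Kinv, S[c1, c1])
        Tm[1, 2] <- Tm[2, 1] <- trace_prod(tm$Kinv, S[c0, c1])
        Bt <- B + Tm
        Gd <- -0.5 * (q * Sinv - Sinv %*% Bt %*% Sinv)
        grad[k:(k + 2)] <- c(Gd[1, 1], 2 * Gd[1, 2], Gd[2, 2])
        Sem <- Bt / q
        em[k:(k + 2)] <- c(Sem[1, 1], Sem[1, 2], Sem[2, 2])
        trCG <- trCG + sum(Sinv * Tm)
        Ut <- U %*% Sinv
        work[, k] <- as.numeric(design$W[, c0] %*% Ut[, 1])
        work[, k + 1] <- as.numeric(design$W[, c0] %*% Ut[, 2] +
                                      design$W[, c1] %*% Ut[, 1])
        work[, k + 2] <- as.numeric(design$W[, c1] %*% Ut[, 2])
        k <- k + 3L
      } else {
        u <- theta[cols]
        Ku <- as.numeric(tm$Kinv %*% u)
        uKu <- sum(u * Ku)
        s2 <- as.numeric(vc$components[[tm$name]])
        Tt <- trace_prod(tm$Kinv, S[cols, cols])
        grad[k] <- -0.5 * (tm$q - (uKu + Tt) / s2) / s2
        em[k] <- (uKu + Tt) / tm$q
        trCG <- trCG + Tt / s2
        work[, k] <- as.numeric(design$W[, cols] %*% u) / s2
        k <- k + 1L
      }
    }
    ## residual
    grad[k] <- -0.5 * ((design$n - design$n_eq + trCG) / s2e - ee_w / s2e^2)
    em[k] <- (ee_w + s2e * (design$n_eq - trCG)) / design$n
    work[, k] <- e / s2e
    ## convert gradient and EM targets from the internal to the raw basis
    grad <- grad * ps
    em <- em / ps

    ## average information from working vectors
    rhs_w <- Matrix::crossprod(design$W, design$w_rec * work) / s2e
    theta_w <- as.matrix(Matrix::solve(cur$chol, rhs_w))
    Pwork <- (design$w_rec * (work - as.matrix(design$W %*% theta_w))) / s2e
    AI <- 0.5 * crossprod(work, Pwork)
    AI <- (AI + t(AI)) / 2
    AI <- AI * outer(ps, ps)

    if (control$verbose)
      message(sprintf("iter %d: logL = %.6f, max|g| = %.3g (%s)",
                      iter, cur$logL, max(abs(grad)), step_type))

    ## convergence check with an active set: a variance drifting towards
    ## zero while the likelihood pushes it down counts as a boundary
    ## estimate (its gradient cannot vanish); such parameters are pinned
    ## at the floor and frozen
    shrink <- var_par & !frozen & th * pscale < 1e-3 * vy & grad < 0
    g_eff <- grad
    g_eff[shrink | frozen] <- 0
    ok <- !(shrink | frozen)
    rel_eff <- if (iter > 1L && any(ok))
      max(abs(th - th_prev)[ok] / (abs(th_prev)[ok] + 1e-10)) else rel_change
    if (iter > 1L && rel_eff < control$tol_param &&
        max(abs(g_eff)) < control$tol_grad) {
      if (any(shrink)) {
        th[shrink] <- flo[shrink]
        frozen <- frozen | shrink
        boundary <- boundary | shrink
        ## a pinned slope variance implies no covariance either
        for (tri in slope_triplets(design$terms))
          if (frozen[tri[1]] || frozen[tri[3]]) {
            th[tri[2]] <- 0; frozen[tri[2]] <- TRUE
          }
        vc <- unpack_params(th, design$terms)
        cur <- reml_loglik(design, vc)
        rel_change <- Inf
        next
      }
      converged <- TRUE
      break
    }

    ## propose AI step, fall back to EM; the trajectory is kept monotone
    th_prev <- th
    th_old <- th
    act <- !frozen
    delta <- tryCatch({
      d <- numeric(n_par)
      d[act] <- solve(AI[act, act, drop = FALSE], grad[act])
      d
    }, error = function(err) NULL)
    took <- FALSE
    if (!is.null(delta)) {
      ## trust region: no parameter moves by more than a few times its
      ## own scale in one step (keeps trial points numerically sane)
      cap <- 3 * (abs(th_old) + 0.1 * vy)
      delta <- sign(delta) * pmin(abs(delta), cap)
      delta[frozen] <- 0
      ## an unconstrained AI proposal driving an already-small variance
      ## negative marks a boundary estimate: pin it at the floor
      ## (only after the first couple of iterations, so a bad start does
      ## not freeze a parameter the joint updates could still rescue)
      neg <- var_par & !frozen & (th_old + delta) < flo &
        th_old * pscale < 1e-2 * vy & grad < 0 & iter > 2L
      if (any(neg)) {
        th[neg] <- flo[neg]
        frozen <- frozen | neg
        boundary <- boundary | neg
        for (tri in slope_triplets(design$terms))
          if (frozen[tri[1]] || frozen[tri[3]]) {
            th[tri[2]] <- 0; frozen[tri[2]] <- TRUE
          }
        vc <- unpack_params(th, design$terms)
        cur <- reml_loglik(design, vc)
        rel_change <- Inf
        next
      }
      for (frac in c(1, 0.5, 0.25, 0.1)) {
        th_ai <- th_old + frac * delta
        if (!params_valid(th_ai, design$terms, floor_v)) next
        vc_ai <- unpack_params(th_ai, design$terms)
        new <- tryCatch(reml_loglik(design, vc_ai),
                        error = function(err) NULL)
        if (is.null(new)) next
        if (is.finite(new$logL) && new$logL >= cur$logL - 1e-6) {
          th <- th_ai; vc <- vc_ai; cur <- new; took <- TRUE
          step_type <- if (frac == 1) "AI" else sprintf("AI/%g", 1 / frac)
          break
        }
      }
    }
    if (!took) {
      th_em <- em
      th_em[frozen] <- flo[frozen]
      pinned <- var_par & th_em < flo   # covariances may be negative
      th_em[pinned] <- flo[pinned]
      ## keep 2x2 blocks PSD after pinning by shrinking covariances
      kk <- 1L
      for (tm in design$terms) {
        if (tm$slope) {
          v0 <- th_em[kk]; c01 <- th_em[kk + 1]; v1 <- th_em[kk + 2]
          lim <- sqrt(v0 * v1) * 0.999
          if (abs(c01) > lim) th_em[kk + 1] <- sign(c01) * lim
          kk <- kk + 3L
        } else kk <- kk + 1L
      }
      ## EM is monotone in exact arithmetic; guard against numerical
      ## degradation by stepping only part-way when needed
      for (frac in c(1, 0.5, 0.25)) {
        th_try <- th_old + frac * (th_em - th_old)
        vc_try <- unpack_params(th_try, design$terms)
        new <- tryCatch(reml_loglik(design, vc_try),
                        error = function(err) NULL)
        if (!is.null(new) && is.finite(new$logL) &&
            new$logL >= cur$logL - 1e-6) {
          boundary <- boundary | (pinned & !grepl("_c01", par_names))
          th <- th_try; vc <- vc_try; cur <- new; took <- TRUE
          step_type <- if (frac == 1) "EM" else sprintf("EM/%g", 1 / frac)
          break
        }
      }
      if (!took) {       # no direction improves: stall at the best point
        converged <- max(abs(g_eff)) < 1e-3
        break
      }
    }
    rel_change <- max(abs(th - th_old)[!frozen] / (abs(th_old)[!frozen] + 1e-10))
  }

  grad[frozen] <- 0   # boundary-pinned parameters: KKT gradient is one-sided
  se <- tryCatch(sqrt(pmax(diag(solve(AI)), 0)), error = function(err)
    rep(NA_real_, n_par))
  sol <- split_solution(c(design, list(sigma2_e = vc$sigma2_e)), cur$theta)
  structure(list(components = vc$components, sigma2_e = vc$sigma2_e,
                 logLik = cur$logL,
                 se = stats::setNames(se, par_names),
                 gradient = stats::setNames(grad, par_names),
                 AI = AI,
                 solutions = sol,
                 converged = converged, iterations = iter,
                 boundary = stats::setNames(boundary, par_names),
                 spec = spec, n_records = design$n),
            class = "vc_fit")
}

#' @export
print.vc_fit <- function(x, ...) {
  cat("REML variance components (", if (x$converged) "converged"
      else "NOT converged", ", ", x$iterations, " iterations)\n", sep = "")
  for (nm in names(x$components)) {
    cmp <- x$components[[nm]]
    if (is.matrix(cmp)) {
      cat(sprintf("  %s: var(a0) = %.4g, cov(a0,a1) = %.4g, var(a1) = %.4g\n",
                  nm, cmp[1, 1], cmp[1, 2], cmp[2, 2]))
    } else cat(sprintf("  %s: %.4g\n", nm, cmp))
  }
  cat(sprintf("  residual: %.4g\n  logLik: %.4f\n", x$sigma2_e, x$logLik))
  invisible(x)
}
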