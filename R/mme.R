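#' Specify a mixed model for the reaction-norm machinery
#'
#' Describes a univariate animal-type model: a response, categorical fixed
#' effects, and random terms that are either scalar (one effect per level)
#' or intercept+slope (a correlated pair of effects per level regressed on a
#' per-record covariable, the estimated herd effect in the reaction norm
#' model). Each random term has a covariance structure: a named kinship
#' inverse (pedigree `A_inv` or single-step `H_inv`) or the identity.
#'
#' @param response Column name of the response.
#' @param fixed Character vector of fixed-effect columns (treated as
#'   factors; identifiability by drop-first/treatment coding).
#' @param random Named list of random terms. Each element is a list with
#'   `column` (grouping column in the data), `structure` (`"kinship"` or
#'   `"identity"`) and `slope` (logical: intercept+slope term; requires
#'   `covariable`).
#' @param covariable Column name of the per-record regressor for slope
#'   terms (`NULL` if none).
#' @param weight_column Optional column of per-record residual weights `w`
#'   (residual variance of a record is `sigma2_e / w`); `NULL` means 1.
#' @return An object of class `rnm_model_spec`.
#' @export
rnm_model_spec <- function(response = "value",
                           fixed = c("herd", "parity", "year", "month", "age_class"),
                           random = list(
                             animal = list(column = "animal",
                                           structure = "kinship", slope = FALSE),
                             herd_year = list(column = "herd_year",
                                              structure = "identity", slope = FALSE),
                             pe = list(column = "animal",
                                       structure = "identity", slope = FALSE)),
                           covariable = NULL,
                           weight_column = NULL) {
  for (nm in names(random)) {
    r <- random[[nm]]
    stopifnot(is.list(r), !is.null(r$column), !is.null(r$structure))
    if (isTRUE(r$slope) && is.null(covariable))
      stop("random term '", nm, "' has a slope but no covariable is given")
    random[[nm]]$slope <- isTRUE(r$slope)
  }
  structure(list(response = response, fixed = fixed, random = random,
                 covariable = covariable, weight_column = weight_column),
            class = "rnm_model_spec")
}

## incidence matrix records x levels
incidence <- function(values, levels) {
  j <- match(as.character(values), levels)
  if (anyNA(j)) stop("design column contains levels with no effect: ",
                     paste(utils::head(unique(values[is.na(j)])), collapse = ", "))
  Matrix::sparseMatrix(i = seq_along(j), j = j, x = 1,
                       dims = c(length(j), length(levels)))
}

## Resolve the design pieces that do not depend on variance components.
## kinships: named list; element for a "kinship"-structure term must be a
## `kinship` of kind A_inv or H_inv (its ids define the level order).
mme_design <- function(spec, data, kinships) {
  y <- data[[spec$response]]
  if (is.null(y)) stop("response column '", spec$response, "' not found")
  n <- length(y)
  fixed_cols <- spec$fixed[vapply(spec$fixed, function(f)
    length(unique(data[[f]])) > 1, logical(1))]
  fml <- if (length(fixed_cols))
    stats::as.formula(paste("~", paste(fixed_cols, collapse = " + ")))
  else stats::as.formula("~ 1")
  fdat <- data[, intersect(names(data), spec$fixed), drop = FALSE]
  for (f in names(fdat)) fdat[[f]] <- factor(fdat[[f]])
  X <- Matrix::sparse.model.matrix(fml, fdat)
  ## drop-first coding handles within-factor identifiability; cross-factor
  ## aliasing (e.g. a year level implied by parity) is removed by pivoted QR
  if (ncol(X) > 1) {
    qx <- qr(as.matrix(X))
    if (qx$rank < ncol(X))
      X <- X[, sort(qx$pivot[seq_len(qx$rank)]), drop = FALSE]
  }
  p <- ncol(X)

  terms <- list()
  Zs <- list()
  offset <- p
  for (nm in names(spec$random)) {
    r <- spec$random[[nm]]
    if (r$structure == "kinship") {
      K <- kinships[[nm]]
      if (is.null(K)) stop("no kinship supplied for random term '", nm, "'")
      levs <- K$ids
      Kinv <- K$values
      logdetK <- -as.numeric(Matrix::determinant(K$values, logarithm = TRUE)$modulus)
    } else {
      levs <- as.character(sort(unique(data[[r$column]])))
      Kinv <- Matrix::Diagonal(length(levs))
      logdetK <- 0
    }
    q <- length(levs)
    Z0 <- incidence(data[[r$column]], levs)
    cv_scale <- 1
    if (r$slope) {
      cv <- data[[spec$covariable]]
      if (is.null(cv)) stop("covariable column '", spec$covariable, "' not found")
      ## the covariable is standardized internally for conditioning; the
      ## slope components and solutions are transformed back on output
      cv_scale <- stats::sd(cv)
      if (!is.finite(cv_scale) || cv_scale < 1e-12) cv_scale <- 1
      Z <- cbind(Z0, Z0 * (cv / cv_scale))  # component-major blocks
      npar <- 3L
    } else {
      Z <- Z0
      npar <- 1L
    }
    terms[[nm]] <- list(name = nm, levels = levs, q = q, slope = r$slope,
                        Kinv = Kinv, logdetK = logdetK, npar = npar,
                        cv_scale = cv_scale,
                        cols = offset + seq_len(ncol(Z)))
    Zs[[nm]] <- Z
    offset <- offset + ncol(Z)
  }
  W <- do.call(cbind, c(list(X), unname(Zs)))
  w_rec <- if (is.null(spec$weight_column)) rep(1, n) else {
    wv <- data[[spec$weight_column]]
    if (any(wv <= 0)) stop("residual weights must be positive")
    wv
  }
  Dw <- Matrix::Diagonal(x = w_rec)
  WtW <- Matrix::forceSymmetric(Matrix::crossprod(W, Dw %*% W))
  Wty <- as.numeric(Matrix::crossprod(W, w_rec * y))
  list(y = y, n = n, X = X, p = p, W = W, terms = terms, w_rec = w_rec,
       WtW = WtW, Wty = Wty, yty = sum(w_rec * y^2),
       sum_log_w = sum(log(w_rec)), n_eq = ncol(W))
}

## Prior (G-side) block-diagonal inverse for given variance components.
## vc: list(components = named list (scalar or 2x2 matrix), sigma2_e)
mme_prior <- function(design, vc) {
  n_eq <- design$n_eq
  blocks <- list()
  logdetG <- 0
  for (tm in design$terms) {
    cmp <- vc$components[[tm$name]]
    if (is.null(cmp)) stop("no variance component for term '", tm$name, "'")
    if (tm$slope) {
      ## convert the (raw-covariable) 2x2 block to the internal basis
      Tm <- diag(c(1, tm$cv_scale))
      S <- Tm %*% as.matrix(cmp) %*% Tm
      Sinv <- solve(S)
      blocks[[tm$name]] <- Matrix::kronecker(Sinv, tm$Kinv)
      logdetG <- logdetG + tm$q * as.numeric(determinant(S)$modulus) +
        2 * tm$logdetK
    } else {
      blocks[[tm$name]] <- tm$Kinv / as.numeric(cmp)
      logdetG <- logdetG + tm$q * log(as.numeric(cmp)) + tm$logdetK
    }
  }
  Gstar <- Matrix::bdiag(c(list(Matrix::Matrix(0, design$p, design$p)),
                           unname(blocks)))
  list(Gstar = Matrix::forceSymmetric(Gstar), logdetG = logdetG)
}

#' Build Henderson's mixed model equations
#'
#' Assembles the sparse symmetric system `C theta = r` with
#' `C = W' R^-1 W + diag(0, G^-1)` where `W = [X Z]`, `R^-1` carries the
#' per-record weights divided by the residual variance, and the prior block
#' is `Kinv / sigma2` for scalar terms or `Sigma^-1 (x) Kinv` for
#' intercept+slope terms (component-major ordering: all intercepts, then
#' all slopes).
#'
#' @param spec An [rnm_model_spec()].
#' @param data Phenotype `data.frame`.
#' @param kinships Named list of `kinship` objects (kind `A_inv` or
#'   `H_inv`) for the kinship-structured terms.
#' @param vc List with `components` (named list of scalar variances or 2x2
#'   matrices, one per random term) and `sigma2_e`.
#' @return A list with the coefficient matrix `C`, right-hand side `rhs`,
#'   and the design bookkeeping needed to interpret solutions.
#' @export
build_mme <- function(spec, data, kinships = list(), vc) {
  design <- mme_design(spec, data, kinships)
  prior <- mme_prior(design, vc)
  C <- design$WtW / vc$sigma2_e + prior$Gstar
  rhs <- design$Wty / vc$sigma2_e
  c(design, list(C = Matrix::forceSymmetric(C), rhs = rhs,
                 sigma2_e = vc$sigma2_e, vc = vc,
                 logdetG = prior$logdetG, Gstar = prior$Gstar))
}

#' Solve mixed model equations
#'
#' Direct sparse Cholesky solve, with a dense solve as fallback if the
#' sparse factorization fails.
#'
#' @param system Output of [build_mme()].
#' @return A list with `theta` (full solution vector), `fixed` (named fixed
#'   effects) and `random` (per term: vector of effects, or a two-column
#'   `a0`/`a1` matrix for slope terms), plus the residuals `e`.
#' @export
solve_mme <- function(system) {
  theta <- tryCatch({
    ch <- ssrnm:::mme_cholesky(system$C)
    as.numeric(Matrix::solve(ch, system$rhs))
  }, error = function(err) {
    as.numeric(solve(as.matrix(system$C), system$rhs))
  })
  split_solution(system, theta)
}

split_solution <- function(system, theta) {
  fixed <- stats::setNames(theta[seq_len(system$p)], colnames(system$X))
  random <- list()
  for (tm in system$terms) {
    th <- theta[tm$cols]
    if (tm$slope) {
      r <- matrix(th, ncol = 2, dimnames = list(tm$levels, c("a0", "a1")))
      r[, "a1"] <- r[, "a1"] / tm$cv_scale    # back to the raw covariable
      random[[tm$name]] <- r
    } else {
      random[[tm$name]] <- stats::setNames(th, tm$levels)
    }
  }
  e <- system$y - as.numeric(system$W %*% theta)
  list(theta = theta, fixed = fixed, random = random, e = e)
}
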