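#' Relationship matrices for single-step evaluation
#'
#' A `kinship` object is a square symmetric matrix over an ordered id list,
#' tagged with the role it plays in the single-step machinery.
#'
#' @param values Square symmetric matrix (base or [Matrix::Matrix]).
#' @param kind One of `"A"`, `"A_inv"`, `"A22"`, `"G0"`, `"G_blend"`,
#'   `"G_adj"`, `"H_inv"`.
#' @param ids Ordered animal ids (no duplicates) labelling rows/columns.
#' @param omega Blending fraction used (for blended/adjusted G and H), in
#'   \[0, 1\]; `NA` otherwise.
#' @return An object of class `kinship`.
#' @export
kinship <- function(values, kind = c("A", "A_inv", "A22", "G0", "G_blend",
                                     "G_adj", "H_inv"),
                    ids, omega = NA_real_) {
  kind <- match.arg(kind)
  ids <- as.character(ids)
  if (anyDuplicated(ids)) stop("duplicated ids in kinship matrix")
  if (nrow(values) != length(ids) || ncol(values) != length(ids))
    stop("kinship dimensions do not match id list")
  if (!is.na(omega) && (omega < 0 || omega > 1))
    stop("omega must lie in [0, 1]")
  dimnames(values) <- list(ids, ids)
  structure(list(values = values, kind = kind, ids = ids, omega = omega),
            class = "kinship")
}

#' @export
print.kinship <- function(x, ...) {
  cat(sprintf("<kinship %s: %d x %d%s>\n", x$kind, length(x$ids),
              length(x$ids),
              if (!is.na(x$omega)) sprintf(", omega = %g", x$omega) else ""))
  invisible(x)
}

#' Per-marker SNP weights
#'
#' The diagonal weight matrix D of the weighted genomic relationship matrix
#' and of the iterative single-step GWAS.
#'
#' @param weights Nonnegative finite per-marker weights.
#' @param iteration Iteration index the weights belong to (0 = identity).
#' @return An object of class `snp_weights`.
#' @export
snp_weights <- function(weights, iteration = 0L) {
  if (any(!is.finite(weights)) || any(weights < 0))
    stop("SNP weights must be finite and nonnegative")
  structure(list(weights = as.numeric(weights),
                 iteration = as.integer(iteration)),
            class = "snp_weights")
}

ped_parent_idx <- function(ped) {
  chk <- check_pedigree(ped)
  list(s = chk$sire_idx, d = chk$dam_idx, n = nrow(ped))
}

#' Numerator relationship matrix (tabular method)
#'
#' @param ped Topologically sorted pedigree (`id`, `sire`, `dam`; 0 =
#'   unknown parent).
#' @return A dense `kinship` of kind `"A"`.
#' @export
build_A <- function(ped) {
  px <- ped_parent_idx(ped)
  n <- px$n
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    s <- px$s[i]; d <- px$d[i]
    if (i > 1) {
      j <- seq_len(i - 1L)
      row <- numeric(i - 1L)
      if (s > 0) row <- row + 0.5 * A[s, j]
      if (d > 0) row <- row + 0.5 * A[d, j]
      A[i, j] <- row
      A[j, i] <- row
    }
    A[i, i] <- 1 + if (s > 0 && d > 0) 0.5 * A[s, d] else 0
  }
  dimnames(A) <- list(ped$id, ped$id)
  kinship(A, "A", ped$id)
}

#' Inbreeding coefficients (Meuwissen-Luo recursion)
#'
#' @param ped Topologically sorted pedigree.
#' @return Numeric vector of inbreeding coefficients, named by id.
#' @export
inbreeding <- function(ped) {
  px <- ped_parent_idx(ped)
  stats::setNames(.ml_inbreeding(px$s - 1L, px$d - 1L), ped$id)
}

#' Sparse inverse of the numerator relationship matrix
#'
#' Henderson's rules with inbreeding accounted for through the
#' Meuwissen-Luo recursion, so that `A_inv %*% A = I` exactly on arbitrary
#' (inbred) pedigrees.
#'
#' @param ped Topologically sorted pedigree.
#' @return A sparse symmetric `kinship` of kind `"A_inv"`.
#' @export
build_A_inverse <- function(ped) {
  px <- ped_parent_idx(ped)
  n <- px$n
  F <- .ml_inbreeding(px$s - 1L, px$d - 1L)
  ## Mendelian sampling variance d_i
  ds <- rep(1, n)
  has_s <- px$s > 0; has_d <- px$d > 0
  ds[has_s] <- ds[has_s] - 0.25 * (1 + F[px$s[has_s]])
  ds[has_d] <- ds[has_d] - 0.25 * (1 + F[px$d[has_d]])
  w <- 1 / ds
  ii <- list(); jj <- list(); xx <- list(); k <- 1L
  add <- function(i, j, x) {
    ii[[k]] <<- i; jj[[k]] <<- j; xx[[k]] <<- x; k <<- k + 1L
  }
  idx <- seq_len(n)
  add(idx, idx, w)
  s <- px$s; d <- px$d
  hs <- which(has_s); hd <- which(has_d); hb <- which(has_s & has_d)
  if (length(hs)) {
    add(hs, s[hs], -0.5 * w[hs]); add(s[hs], hs, -0.5 * w[hs])
    add(s[hs], s[hs], 0.25 * w[hs])
  }
  if (length(hd)) {
    add(hd, d[hd], -0.5 * w[hd]); add(d[hd], hd, -0.5 * w[hd])
    add(d[hd], d[hd], 0.25 * w[hd])
  }
  if (length(hb)) {
    add(s[hb], d[hb], 0.25 * w[hb]); add(d[hb], s[hb], 0.25 * w[hb])
  }
  Ainv <- Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj),
                               x = unlist(xx), dims = c(n, n),
                               dimnames = list(ped$id, ped$id))
  Ainv <- Matrix::forceSymmetric(Matrix::drop0(Ainv))
  kinship(Ainv, "A_inv", ped$id)
}

#' Pedigree relationships among genotyped animals
#'
#' Restricts A to the genotyped ids, in the order given (the order of the
#' genotype matrix).
#'
#' @param A `kinship` of kind `"A"`.
#' @param genotyped_ids Ids to keep.
#' @return Dense `kinship` of kind `"A22"`.
#' @export
subset_A22 <- function(A, genotyped_ids) {
  stopifnot(inherits(A, "kinship"), A$kind == "A")
  genotyped_ids <- as.character(genotyped_ids)
  pos <- match(genotyped_ids, A$ids)
  if (anyNA(pos)) stop("unknown ids in genotyped_ids: ",
                       paste(utils::head(genotyped_ids[is.na(pos)]), collapse = ", "))
  kinship(as.matrix(A$values)[pos, pos, drop = FALSE], "A22", genotyped_ids)
}

## Centered genotype matrix Z and allele frequencies, with monomorphic
## markers dropped from both Z and the denominator.
center_genotypes <- function(geno) {
  G <- if (inherits(geno, "snp_geno")) geno$genotypes else geno
  p <- colMeans(G) / 2
  keep <- p > 0 & p < 1
  if (!any(keep)) stop("all markers are monomorphic: zero denominator")
  Z <- sweep(G[, keep, drop = FALSE], 2, 2 * p[keep])
  list(Z = Z, p = p[keep], keep = which(keep),
       het = 2 * p[keep] * (1 - p[keep]))
}

#' Marker-based genomic relationship matrix
#'
#' `G0 = Z D Z' / sum(2 p_i (1 - p_i))` over polymorphic markers, with Z
#' columns centred by twice the allele frequency computed from the supplied
#' genotypes. Monomorphic markers are excluded from Z and from the
#' denominator.
#'
#' @param geno A `snp_geno` object or a plain 0/1/2 matrix with ids as
#'   rownames.
#' @param D Optional [snp_weights()] (full marker panel length); identity
#'   when `NULL`.
#' @return Dense `kinship` of kind `"G0"`.
#' @export
build_G0 <- function(geno, D = NULL) {
  cg <- center_genotypes(geno)
  w <- if (is.null(D)) rep(1, length(cg$keep)) else {
    if (length(D$weights) == length(cg$keep)) D$weights
    else D$weights[cg$keep]
  }
  denom <- sum(cg$het)
  G0 <- tcrossprod(sweep(cg$Z, 2, w, `*`), cg$Z) / denom
  G0 <- (G0 + t(G0)) / 2
  kinship(G0, "G0", rownames(cg$Z))
}

#' Blend the genomic matrix with pedigree relationships
#'
#' `G = (1 - omega) G0 + omega A22`. The default `omega = 0.2` represents
#' the fraction of genetic variance not captured by the markers and also
#' guarantees that G is invertible when A22 is full rank.
#'
#' @param G0,A22 Conformable `kinship` objects over the same ids.
#' @param omega Blending fraction in \[0, 1\].
#' @return Dense `kinship` of kind `"G_blend"`.
#' @export
blend_G <- function(G0, A22, omega = 0.2) {
  if (omega < 0 || omega > 1) stop("omega must lie in [0, 1]")
  if (!identical(G0$ids, A22$ids))
    stop("G0 and A22 must share the same id order")
  kinship((1 - omega) * as.matrix(G0$values) + omega * as.matrix(A22$values),
          "G_blend", G0$ids, omega = omega)
}

#' Rescale G to be compatible with A22
#'
#' Two-moment adjustment: returns `beta * G + alpha` with the scalars
#' solving `mean(diag(beta G + alpha)) = mean(diag(A22))` and
#' `mean(beta G + alpha) = mean(A22)`.
#'
#' @param G,A22 Conformable `kinship` objects over the same ids.
#' @return Dense `kinship` of kind `"G_adj"`.
#' @export
adjust_G_to_A22 <- function(G, A22) {
  if (!identical(G$ids, A22$ids))
    stop("G and A22 must share the same id order")
  Gm <- as.matrix(G$values); Am <- as.matrix(A22$values)
  md_g <- mean(diag(Gm)); mo_g <- mean(Gm)
  md_a <- mean(diag(Am)); mo_a <- mean(Am)
  if (abs(md_g - mo_g) < 1e-12) {
    warning("degenerate adjustment system (mean diagonal equals overall mean); returning G unchanged")
    return(kinship(Gm, "G_adj", G$ids, omega = G$omega))
  }
  beta <- (md_a - mo_a) / (md_g - mo_g)
  alpha <- md_a - beta * md_g
  kinship(beta * Gm + alpha, "G_adj", G$ids, omega = G$omega)
}

#' Inverse of the combined pedigree-genomic relationship matrix
#'
#' `H_inv = A_inv + [0 0; 0 G_inv - A22_inv]` on the genotyped block.
#' Reduces to `A_inv` when no animal is genotyped or when `G = A22`.
#'
#' @param A_inv Sparse `kinship` of kind `"A_inv"` over the full pedigree.
#' @param G_adj Blended/adjusted genomic `kinship` over the genotyped ids
#'   (must be invertible; blend with `omega > 0` if not).
#' @param A22 Pedigree `kinship` over the same genotyped ids.
#' @param genotyped_ids Ids of the genotyped animals (G/A22 order).
#' @return Sparse symmetric `kinship` of kind `"H_inv"`.
#' @export
build_H_inverse <- function(A_inv, G_adj, A22, genotyped_ids = G_adj$ids) {
  genotyped_ids <- as.character(genotyped_ids)
  if (length(genotyped_ids) == 0)
    return(kinship(A_inv$values, "H_inv", A_inv$ids))
  pos <- match(genotyped_ids, A_inv$ids)
  if (anyNA(pos)) stop("genotyped ids absent from the pedigree")
  Gm <- as.matrix(G_adj$values)
  Am <- as.matrix(A22$values)
  Ginv <- tryCatch(chol2inv(chol(Gm)), error = function(e)
    stop("G is singular; blend with omega > 0 before inverting"))
  corr <- Ginv - chol2inv(chol(Am))
  corr <- (corr + t(corr)) / 2
  n <- length(A_inv$ids)
  Cs <- Matrix::sparseMatrix(i = rep(pos, times = length(pos)),
                             j = rep(pos, each = length(pos)),
                             x = as.vector(corr), dims = c(n, n))
  Hinv <- Matrix::forceSymmetric(A_inv$values + Cs)
  dimnames(Hinv) <- list(A_inv$ids, A_inv$ids)
  kinship(Hinv, "H_inv", A_inv$ids, omega = G_adj$omega)
}

#' Write a sparse kinship matrix in coordinate form
#'
#' Row id, column id, value TSV of the nonzero (lower-triangle) entries.
#'
#' @param K `kinship` object with sparse values.
#' @param path Output TSV path.
#' @export
write_kinship_coo <- function(K, path) {
  M <- Matrix::tril(methods::as(methods::as(K$values, "generalMatrix"), "TsparseMatrix"))
  df <- data.frame(row = K$ids[M@i + 1L], col = K$ids[M@j + 1L], value = M@x)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
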