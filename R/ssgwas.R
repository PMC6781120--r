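#' Back-solve SNP effects from genomic breeding values
#'
#' `u_hat = D Z' (Z D Z')^-1 a_hat`, where Z is the centred genotype matrix
#' of the genotyped animals and `a_hat` their (combined or per-component)
#' genomic breeding values. Because Z's columns are centred at frequencies
#' computed from the same animals, `Z D Z'` always has the ones-vector in
#' its null space (rank at most n - 1): the inverse is taken as an
#' eigenvalue-truncated pseudo-inverse, which is exact on the range space,
#' so `Z u_hat` reproduces the mean-centred breeding values exactly (the
#' overall mean is not attributable to centred marker covariates).
#'
#' @param Z Centred genotype matrix (animals x markers).
#' @param a_hat Breeding values of the genotyped animals (Z's row order).
#' @param D Optional [snp_weights()] over Z's markers (identity if `NULL`).
#' @param iteration Iteration index stored on the result.
#' @return An object of class `snp_effects`: `u` (per-marker effects),
#'   `weights` used, `iteration`.
#' @export
backsolve_snp_effects <- function(Z, a_hat, D = NULL, iteration = 0L) {
  if (length(a_hat) != nrow(Z))
    stop("length of a_hat does not match the number of genotyped animals")
  d <- if (is.null(D)) rep(1, ncol(Z)) else D$weights
  if (length(d) != ncol(Z)) stop("SNP weight length does not match markers")
  ZD <- sweep(Z, 2, d, `*`)
  ZDZt <- tcrossprod(ZD, Z)
  ZDZt <- (ZDZt + t(ZDZt)) / 2
  ev <- eigen(ZDZt, symmetric = TRUE)
  keep <- ev$values > 1e-10 * max(ev$values, 0) & ev$values > 0
  if (!any(keep)) stop("Z D Z' has no positive eigenvalues")
  V <- ev$vectors[, keep, drop = FALSE]
  sol <- V %*% (crossprod(V, a_hat) / ev$values[keep])
  u <- as.numeric(crossprod(ZD, sol))
  structure(list(u = u, weights = d, iteration = as.integer(iteration)),
            class = "snp_effects")
}

#' Update SNP weights from back-solved effects
#'
#' Raw weights `D_ii = u_i^2 * 2 p_i (1 - p_i)`, floored at `1e-8` of the
#' mean weight for zero-effect markers, then normalised so that
#' `sum(D_ii * 2 p_i (1 - p_i))` keeps the value it has under identity
#' weights (`sum(2 p_i (1 - p_i))`), i.e. the total genetic variance
#' implied by the weighted genomic matrix stays constant across iterations.
#'
#' @param u Per-marker effects.
#' @param p Allele frequencies.
#' @param iteration Iteration index stored on the result.
#' @return A [snp_weights()].
#' @export
update_snp_weights <- function(u, p, iteration = 0L) {
  stopifnot(length(u) == length(p))
  het <- 2 * p * (1 - p)
  w <- u^2 * het
  if (all(w == 0)) {
    warning("all SNP effects are zero; returning identity weights")
    return(snp_weights(rep(1, length(u)), iteration))
  }
  w <- pmax(w, 1e-8 * mean(w))
  w <- w * sum(het) / sum(w * het)
  snp_weights(w, iteration)
}

#' Per-window percentages of genetic variance
#'
#' Markers are cut into non-overlapping windows of `window` adjacent SNPs
#' per chromosome; leftover markers (fewer than `window`) at the end of a
#' chromosome are merged into that chromosome's last window. The genetic
#' value of window t is `a_t = sum_k Z_k u_k` over its markers (centred
#' genotype columns of the genotyped animals) and the window explains
#' `Var(a_t) / sigma2_a * 100` percent of the genetic variance, with
#' `sigma2_a` the REML estimate for the component (intercept or slope).
#'
#' @param u Per-marker effects (one component).
#' @param Z Centred genotype matrix (same markers).
#' @param map `data.frame` with `chrom` and `pos` per marker (sorted).
#' @param sigma2_a Total additive genetic variance of the component.
#' @param window Window size in SNPs.
#' @return `data.frame` with `window`, `chrom`, `first`, `last` (marker
#'   indices), `start`, `end` (positions), `size`, `pct_var`, ordered along
#'   the genome.
#' @export
window_variance_percentages <- function(u, Z, map, sigma2_a, window = 20L) {
  m <- length(u)
  stopifnot(ncol(Z) == m, nrow(map) == m)
  res <- NULL
  wid <- 0L
  for (ch in unique(map$chrom)) {
    idx <- which(map$chrom == ch)
    if (any(diff(map$pos[idx]) < 0))
      stop("marker map must be sorted by position within chromosome ", ch)
    nw <- max(1L, length(idx) %/% window)
    starts <- (seq_len(nw) - 1L) * window + 1L
    ends <- c(starts[-1L] - 1L, length(idx))   # last window absorbs leftovers
    for (k in seq_len(nw)) {
      wid <- wid + 1L
      sel <- idx[starts[k]:ends[k]]
      av <- as.numeric(Z[, sel, drop = FALSE] %*% u[sel])
      res <- rbind(res, data.frame(
        window = wid, chrom = ch, first = sel[1], last = sel[length(sel)],
        start = map$pos[sel[1]], end = map$pos[sel[length(sel)]],
        size = length(sel),
        pct_var = 100 * stats::var(av) / sigma2_a))
    }
  }
  rownames(res) <- NULL
  res
}

#' Iterative weighted single-step GWAS for reaction norm components
#'
#' Runs the single-step GWAS loop: build the (SNP-weighted) genomic matrix,
#' blend and adjust it, form the H inverse, solve the reaction norm mixed
#' model, combine each genotyped animal's intercept and slope into a
#' breeding value at its mean daughter gradient, back-solve SNP effects
#' from those breeding values, and re-weight markers; after `n_iter`
#' iterations the intercept and slope effects are back-solved separately
#' from `a0` and `a1` and decomposed into per-window variance percentages.
#' Variance components are estimated once (REML with the identity-weight H)
#' and held fixed within the loop, where only the BLUP solutions are
#' refreshed; set `reestimate_vc = TRUE` to re-estimate them at every
#' iteration.
#'
#' @param data Edited phenotype `data.frame`.
#' @param pedigree Pedigree `data.frame`.
#' @param geno `snp_geno` or genotype matrix (rownames = ids) of the
#'   genotyped animals.
#' @param f Named herd-effect vector (step 1).
#' @param groups Optional `residual_groups` (step 2).
#' @param genotyped_ids Ids of genotyped animals.
#' @param vc Optional variance components (an `rnm_fit`'s `vc`); estimated
#'   when `NULL`.
#' @param n_iter Number of weighting iterations.
#' @param omega Blending fraction for G.
#' @param window Window size in SNPs.
#' @param reestimate_vc Re-run REML inside the loop.
#' @param control A [reml_control()].
#' @return A list with `effects` (`data.frame`: marker, chrom, pos, `u0`,
#'   `u1`, final `weight`), `windows` (per-window `pct_var_intercept`,
#'   `pct_var_slope`), the per-iteration combined `snp_effects`, the final
#'   `rnm` solutions and the variance components used.
#' @export
run_ssgwas <- function(data, pedigree, geno, f, groups = NULL,
                       genotyped_ids = NULL, vc = NULL, n_iter = 3L,
                       omega = 0.2, window = 20L, reestimate_vc = FALSE,
                       control = reml_control()) {
  G <- if (inherits(geno, "snp_geno")) geno$genotypes else geno
  map <- if (inherits(geno, "snp_geno")) geno$map else
    data.frame(marker = paste0("snp", seq_len(ncol(G))), chrom = 1L,
               pos = seq_len(ncol(G)))
  if (is.null(genotyped_ids)) genotyped_ids <- rownames(G)
  genotyped_ids <- as.character(genotyped_ids)
  Gg <- G[genotyped_ids, , drop = FALSE]
  cg <- center_genotypes(Gg)
  Z <- cg$Z
  map <- map[cg$keep, , drop = FALSE]

  Ainv <- build_A_inverse(pedigree)
  A <- build_A(pedigree)
  A22 <- subset_A22(A, genotyped_ids)
  D <- snp_weights(rep(1, ncol(Z)), 0L)
  D_used <- D
  effects_by_iter <- list()
  fit <- NULL
  for (it in seq_len(n_iter)) {
    D_used <- D
    G0 <- build_G0(Gg, D)
    Gb <- blend_G(G0, A22, omega)
    Ga <- adjust_G_to_A22(Gb, A22)
    Hinv <- build_H_inverse(Ainv, Ga, A22, genotyped_ids)
    if (is.null(vc) || reestimate_vc) {
      fit <- step3_fit_rnm(data, f, groups, Hinv, control = control,
                           fit_rm = FALSE)
      vc <- fit$vc
    } else {
      fit <- refit_rnm_blup(data, f, groups, Hinv, vc)
    }
    fbar <- mean_daughter_eg(genotyped_ids, pedigree, data, f)
    a_hat <- combine_ebv(fit$a0[genotyped_ids], fit$a1[genotyped_ids],
                         fbar[genotyped_ids])
    eff <- backsolve_snp_effects(Z, a_hat, D, iteration = it)
    eff$a_hat <- unname(a_hat)
    effects_by_iter[[it]] <- eff
    D <- update_snp_weights(eff$u, cg$p, iteration = it)
  }
  ## per-component effects with the weights used in the final iteration
  u0 <- backsolve_snp_effects(Z, unname(fit$a0[genotyped_ids]), D_used,
                              iteration = n_iter)$u
  u1 <- backsolve_snp_effects(Z, unname(fit$a1[genotyped_ids]), D_used,
                              iteration = n_iter)$u
  g2 <- fit$genetic
  w0 <- window_variance_percentages(u0, Z, map, g2[1, 1], window)
  w1 <- window_variance_percentages(u1, Z, map, g2[2, 2], window)
  windows <- w0[, c("window", "chrom", "first", "last", "start", "end", "size")]
  windows$pct_var_intercept <- w0$pct_var
  windows$pct_var_slope <- w1$pct_var
  list(effects = data.frame(marker = map$marker, chrom = map$chrom,
                            pos = map$pos, u0 = u0, u1 = u1,
                            weight = D_used$weights),
       windows = windows, iterations = effects_by_iter,
       rnm = fit, vc = vc, genotyped_ids = genotyped_ids,
       marker_index = cg$keep)
}

## Solve the step-3 RNM for new BLUP solutions at fixed variance components.
refit_rnm_blup <- function(data, f, groups, kinship, vc) {
  data <- add_age_class(data)
  data$eg <- unname(f[as.character(data$herd)])
  data$w <- if (is.null(groups)) 1 else
    groups$weights[groups$herd_group[as.character(data$herd)]]
  spec <- rnm_model_spec(response = "value", fixed = default_fixed,
    random = list(animal = list(column = "animal", structure = "kinship",
                                slope = TRUE),
                  herd_year = list(column = "herd_year",
                                   structure = "identity", slope = FALSE),
                  pe = list(column = "animal", structure = "identity",
                            slope = FALSE)),
    covariable = "eg", weight_column = "w")
  sys <- build_mme(spec, data, list(animal = kinship),
                   list(components = vc$components, sigma2_e = vc$sigma2_e))
  sol <- solve_mme(sys)
  a <- sol$random$animal
  structure(list(vc = vc, genetic = vc$components$animal,
                 sigma2_pe = vc$components$pe,
                 sigma2_hy = vc$components$herd_year,
                 sigma2_e = vc$sigma2_e,
                 a0 = a[, "a0"], a1 = a[, "a1"], f = f, groups = groups,
                 solutions = sol,
                 logLik_rnm = NA_real_, logLik_rm = NA_real_,
                 kinship_kind = kinship$kind),
            class = "rnm_fit")
}
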