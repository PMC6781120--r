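#' Editing rules for fertility records
#'
#' Per-trait censoring penalties, value bounds and age windows, plus the
#' herd-year merging policy. Defaults implement routine fertility-trait
#' editing: censored interval-from-first-to-last-insemination (IFL) records
#' get +40 days, censored insemination counts (AIS) get +1; AIS is bounded
#' to \[1, 5\], IFL to \[0, 365\] days, calving-to-first-insemination (ICF)
#' to \[20, 230\] days, non-return rate (NRR) to \[0, 1\]; age at first
#' insemination must lie in \[270, 900\] days (age at first calving in
#' \[500, 1100\] for ICF); days open (ICF + IFL) must lie in \[20, 365\];
#' values below a lower limit remove the record, values above an upper
#' limit are capped; herd-year classes with fewer than `herd_year_min`
#' records are merged with the nearest year level of the same herd (two
#' passes), then still-small classes are discarded. The synthetic trait
#' `"SIM"` is unit-scale with no penalty and unbounded values, so only the
#' structural rules act on simulated data.
#'
#' @param herd_year_min Minimum records per herd-year class.
#' @param merge_passes Number of nearest-neighbour merge passes.
#' @return An object of class `edit_rules`.
#' @export
edit_rules <- function(herd_year_min = 20L, merge_passes = 2L) {
  traits <- data.frame(
    trait = c("AIS", "IFL", "ICF", "NRR", "SIM"),
    censor_penalty = c(1, 40, 0, 0, 0),
    lower = c(1, 0, 20, 0, -Inf),
    upper = c(5, 365, 230, 1, Inf),
    age_lower = c(270, 270, 500, 270, 270),
    age_upper = c(900, 900, 1100, 900, 900),
    stringsAsFactors = FALSE)
  structure(list(traits = traits,
                 days_open_window = c(20, 365),
                 herd_year_min = as.integer(herd_year_min),
                 merge_passes = as.integer(merge_passes)),
            class = "edit_rules")
}

#' Edit raw phenotype records
#'
#' Applies, in order: censoring penalties; the age window (records outside
#' removed); trait-value bounds (below-lower removed, above-upper capped);
#' the days-open window when ICF and IFL both exist for an animal-parity
#' (below-lower removes the pair, above-upper caps IFL); removal of animals
#' with records in more than one herd within a parity (herd changers); and
#' herd-year merging (two passes of merging classes under the minimum with
#' the nearest year level of the same herd, ties to the earlier year,
#' followed by discarding classes still under the minimum).
#'
#' @param raw Phenotype `data.frame` with at least `animal`, `trait`,
#'   `value`, `censored`, `herd`, `herd_year`, `parity`, `year`, `age_days`.
#' @param rules An [edit_rules()].
#' @return The edited `data.frame`, with an `"edit_log"` attribute counting
#'   what each step did.
#' @export
edit_records <- function(raw, rules = edit_rules()) {
  unknown <- setdiff(unique(raw$trait), rules$traits$trait)
  if (length(unknown))
    stop("unknown trait name(s): ", paste(unknown, collapse = ", "))
  log <- list(n_in = nrow(raw))
  tr <- rules$traits[match(raw$trait, rules$traits$trait), ]

  ## 1. censoring penalties
  pen <- ifelse(raw$censored, tr$censor_penalty, 0)
  raw$value <- raw$value + pen
  log$penalised <- sum(pen != 0)

  ## 2. age window
  keep <- raw$age_days >= tr$age_lower & raw$age_days <= tr$age_upper
  log$age_removed <- sum(!keep)
  raw <- raw[keep, ]; tr <- tr[keep, ]

  ## 3. value bounds
  below <- raw$value < tr$lower
  log$below_removed <- sum(below)
  raw <- raw[!below, ]; tr <- tr[!below, ]
  above <- raw$value > tr$upper
  raw$value[above] <- tr$upper[above]
  log$capped <- sum(above)

  ## 4. days-open window (needs ICF and IFL for the same animal-parity)
  if (all(c("ICF", "IFL") %in% raw$trait)) {
    key <- paste(raw$animal, raw$parity)
    icf <- raw$trait == "ICF"; ifl <- raw$trait == "IFL"
    do_icf <- stats::setNames(raw$value[icf], key[icf])
    pos_ifl <- which(ifl)[key[ifl] %in% names(do_icf)]
    if (length(pos_ifl)) {
      dopen <- raw$value[pos_ifl] + do_icf[key[pos_ifl]]
      lowcut <- dopen < rules$days_open_window[1]
      highcut <- dopen > rules$days_open_window[2]
      raw$value[pos_ifl[highcut]] <-
        rules$days_open_window[2] - do_icf[key[pos_ifl[highcut]]]
      drop_keys <- key[pos_ifl[lowcut]]
      drop <- key %in% drop_keys & (icf | ifl)
      log$days_open_removed <- sum(drop)
      log$days_open_capped <- sum(highcut)
      raw <- raw[!drop, ]
    }
  }

  ## 5. herd changers within a parity
  key <- paste(raw$animal, raw$trait, raw$parity)
  nherd <- tapply(raw$herd, key, function(h) length(unique(h)))
  movers <- unique(raw$animal[key %in% names(nherd)[nherd > 1]])
  log$herd_changers_removed <- sum(raw$animal %in% movers)
  raw <- raw[!raw$animal %in% movers, ]

  ## 6. herd-year merging, per trait
  for (t in unique(raw$trait)) {
    sel <- raw$trait == t
    hy <- merge_herd_years(raw$herd[sel], raw$year[sel],
                           rules$herd_year_min, rules$merge_passes)
    raw$herd_year[sel] <- hy$label
    drop <- sel
    drop[sel] <- hy$discard
    log$herd_year_discarded <- sum(drop) + (log$herd_year_discarded %||% 0)
    raw <- raw[!drop, ]
  }
  log$n_out <- nrow(raw)
  attr(raw, "edit_log") <- log
  rownames(raw) <- NULL
  raw
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## Merge herd-year classes with < min_n records into the nearest year level
## of the same herd (ties to the earlier year), n_passes times; flag classes
## still under the minimum for discarding.
merge_herd_years <- function(herd, year, min_n = 20L, n_passes = 2L) {
  year <- as.integer(year)
  cur_year <- year                      # effective (merged) year level
  for (pass in seq_len(n_passes)) {
    for (h in unique(herd)) {
      sel <- herd == h
      repeat {
        tab <- table(cur_year[sel])
        lv <- as.integer(names(tab))
        small <- lv[tab < min_n]
        if (length(small) == 0 || length(lv) == 1) break
        y0 <- small[1]
        others <- setdiff(lv, y0)
        dd <- abs(others - y0)
        target <- others[dd == min(dd)]
        target <- min(target)           # tie -> earlier year
        cur_year[sel & cur_year == y0] <- target
      }
    }
  }
  label <- paste(herd, cur_year, sep = "-")
  tab <- table(label)
  discard <- label %in% names(tab)[tab < min_n]
  list(label = label, discard = discard, merged_year = cur_year)
}

## age classes for model fitting (factor derived from age in days)
add_age_class <- function(data) {
  if (!"age_class" %in% names(data))
    data$age_class <- cut(data$age_days, AGE_CLASS_BREAKS,
                          right = FALSE, labels = FALSE)
  data
}

default_fixed <- c("herd", "parity", "year", "month", "age_class")

step1_spec <- function(fixed = default_fixed) {
  rnm_model_spec(response = "value", fixed = fixed,
                 random = list(
                   animal = list(column = "animal", structure = "kinship",
                                 slope = FALSE),
                   herd_year = list(column = "herd_year",
                                    structure = "identity", slope = FALSE),
                   pe = list(column = "animal", structure = "identity",
                             slope = FALSE)))
}

#' Step 1: estimate herd effects with a univariate animal model
#'
#' Fits the linear mixed model with fixed herd, parity, year, month and age
#' class, and random additive-genetic (pedigree A or single-step H),
#' herd-year and permanent environmental effects, by REML. Herd effects are
#' returned as estimable contrasts centred to mean zero across herds; they
#' serve as the environmental gradient of the reaction norm in step 3.
#'
#' @param data Edited phenotype `data.frame`.
#' @param kinship `kinship` inverse (`A_inv` or `H_inv`) over the pedigree.
#' @param fixed Fixed-effect columns (must include `"herd"`).
#' @param control A [reml_control()].
#' @return A list with `f` (named herd-effect vector, mean zero), `vc` (the
#'   `vc_fit`) and the model `spec`.
#' @export
step1_herd_effects <- function(data, kinship, fixed = default_fixed,
                               control = reml_control()) {
  stopifnot("herd" %in% fixed)
  data <- add_age_class(data)
  spec <- step1_spec(fixed)
  fit <- reml_estimate(spec, data, list(animal = kinship), control = control)
  herds <- sort(unique(data$herd))
  fe <- fit$solutions$fixed
  f <- stats::setNames(numeric(length(herds)), herds)
  nm <- paste0("herd", herds)
  got <- nm %in% names(fe)
  f[got] <- fe[nm[got]]                 # drop-first coding: first herd is 0
  f <- f - mean(f)
  list(f = f, vc = fit, spec = spec)
}

#' Step 2: residual-variance groups and weights
#'
#' Herds are ranked by their estimated effects and divided into groups at
#' the record-weighted 10/30/70/90% quantiles. The step-1 model is re-run
#' as a Gibbs sampler with a separate residual variance per group
#' ([gibbs_residual_variances()]), and each group's weight is
#' `w_i = sum(n_i sigma2_ei) / (sigma2_ei * sum(n_i))`, so that weighting
#' preserves the record-weighted mean residual variance.
#'
#' @param data Edited phenotype `data.frame`.
#' @param f Named herd-effect vector from [step1_herd_effects()].
#' @param kinship `kinship` inverse used in step 1.
#' @param init Starting components for the sampler (typically step-1 REML
#'   estimates).
#' @param quantiles Group cut points (cumulative record fractions).
#' @param rounds,burnin,thin Gibbs chain settings.
#' @return An object of class `residual_groups`: per-herd `herd_group`,
#'   per-group record counts `n`, posterior-mean `sigma2_e`, `weights`, the
#'   `gibbs_fit`, and the quantile `cuts`.
#' @export
step2_groups_and_weights <- function(data, f, kinship, init = NULL,
                                     quantiles = c(0.10, 0.30, 0.70, 0.90),
                                     rounds = 20000L, burnin = 5000L,
                                     thin = 10L) {
  data <- add_age_class(data)
  herds <- as.integer(names(f))
  counts <- tabulate(match(data$herd, herds), nbins = length(herds))
  grp <- eg_group_values(f, counts, quantiles)
  rec_group <- grp[match(data$herd, herds)]
  gf <- gibbs_residual_variances(step1_spec(), data,
                                 list(animal = kinship),
                                 groups = rec_group, init = init,
                                 rounds = rounds, burnin = burnin,
                                 thin = thin)
  structure(list(herd_group = stats::setNames(grp, herds),
                 n = gf$n_per_group,
                 sigma2_e = unname(gf$group_variances),
                 weights = residual_weights(gf$n_per_group,
                                            gf$group_variances),
                 gibbs = gf, cuts = quantiles), class = "residual_groups")
}

## group index per herd from record-weighted quantiles of herd values
eg_group_values <- function(f, counts, quantiles = c(0.10, 0.30, 0.70, 0.90)) {
  ord <- order(f)
  cum <- cumsum(counts[ord])
  mid <- (cum - counts[ord] / 2) / sum(counts)  # midpoint of each herd's mass
  g <- integer(length(f))
  g[ord] <- findInterval(mid, quantiles, left.open = TRUE) + 1L
  g
}

#' Residual weights from group variances
#'
#' `w_i = sum(n_i sigma2_ei) / (sigma2_ei * sum(n_i))`: the record-weighted
#' mean residual variance divided by the group's variance.
#'
#' @param n Records per group.
#' @param sigma2 Residual variance per group.
#' @return Weight per group.
#' @export
residual_weights <- function(n, sigma2) {
  stopifnot(length(n) == length(sigma2), all(sigma2 > 0))
  as.numeric(sum(n * sigma2) / (sigma2 * sum(n)))
}

#' Step 3: fit the reaction norm model and its reduced model
#'
#' Fits the reaction norm model: fixed effects as in step 1, a correlated
#' (intercept, slope) additive-genetic term with the step-1 herd effects as
#' the covariable, random herd-year and permanent environmental effects,
#' and residual variance `sigma2_e / w_i` with the step-2 group weights.
#' The reduced model (no slope term) is fitted on identical data and
#' weights so that the likelihood-ratio test compares models differing only
#' in the genotype-by-environment term.
#'
#' @param data Edited phenotype `data.frame`.
#' @param f Named herd-effect vector from step 1.
#' @param groups `residual_groups` from step 2 (`NULL` for unit weights and
#'   a single group).
#' @param kinship `kinship` inverse (`A_inv` or `H_inv`).
#' @param fixed Fixed-effect columns.
#' @param control A [reml_control()].
#' @param fit_rm Also fit the reduced model (set `FALSE` to skip).
#' @param init Optional starting components for the reaction norm REML
#'   (ignored when `fit_rm = TRUE`, where the reduced-model optimum is the
#'   start).
#' @return An object of class `rnm_fit` with the 2x2 genetic covariance
#'   block, all variance components and standard errors, per-animal `a0`
#'   and `a1`, herd effects `f`, the `groups`, and the REML log-likelihoods
#'   of both models.
#' @export
step3_fit_rnm <- function(data, f, groups = NULL, kinship,
                          fixed = default_fixed,
                          control = reml_control(), fit_rm = TRUE,
                          init = NULL) {
  data <- add_age_class(data)
  data$eg <- unname(f[as.character(data$herd)])
  if (anyNA(data$eg)) stop("records in herds without a step-1 herd effect")
  if (is.null(groups)) {
    data$w <- 1
  } else {
    data$w <- groups$weights[groups$herd_group[as.character(data$herd)]]
  }
  spec_rnm <- rnm_model_spec(response = "value", fixed = fixed,
    random = list(animal = list(column = "animal", structure = "kinship",
                                slope = TRUE),
                  herd_year = list(column = "herd_year",
                                   structure = "identity", slope = FALSE),
                  pe = list(column = "animal", structure = "identity",
                            slope = FALSE)),
    covariable = "eg", weight_column = "w")
  rm_fit <- NULL
  if (fit_rm) {
    spec_rm <- rnm_model_spec(response = "value", fixed = fixed,
      random = list(animal = list(column = "animal", structure = "kinship",
                                  slope = FALSE),
                    herd_year = list(column = "herd_year",
                                     structure = "identity", slope = FALSE),
                    pe = list(column = "animal", structure = "identity",
                              slope = FALSE)),
      weight_column = "w")
    rm_fit <- reml_estimate(spec_rm, data, list(animal = kinship),
                            control = control)
  }
  fit <- reml_estimate(spec_rnm, data, list(animal = kinship),
                       init = init, control = control)
  ## a slope variance on the boundary can be a basin of the optimizer
  ## rather than the data: retry once from a G x E-present start and keep
  ## the better restricted likelihood
  vy <- stats::var(data$value)
  veg <- stats::var(data$eg)
  if (!is.finite(veg) || veg < 1e-12) veg <- 1
  if (fit$components$animal[2, 2] <= 1e-6 * vy / veg) {
    v0 <- fit$components$animal[1, 1]
    init_g <- list(components = list(
      animal = matrix(c(v0, 0, 0, 0.3 * v0 / veg), 2, 2),
      herd_year = fit$components$herd_year,
      pe = fit$components$pe), sigma2_e = fit$sigma2_e)
    refit <- reml_estimate(spec_rnm, data, list(animal = kinship),
                           init = init_g, control = control)
    if (refit$logLik > fit$logLik) fit <- refit
  }
  if (fit_rm && fit$logLik < rm_fit$logLik - 1e-6) {
    ## the reaction norm can never genuinely fit worse than its nested
    ## reduced model: restart the REML from the reduced-model optimum with
    ## the slope variance at the boundary floor, where monotone ascent
    ## preserves the nested-likelihood ordering, and keep the better fit
    v0 <- as.numeric(rm_fit$components$animal)
    init2 <- list(components = list(
      animal = matrix(c(v0, 0, 0, 2e-8 * vy / veg), 2, 2),
      herd_year = rm_fit$components$herd_year,
      pe = rm_fit$components$pe), sigma2_e = rm_fit$sigma2_e)
    refit <- reml_estimate(spec_rnm, data, list(animal = kinship),
                           init = init2, control = control)
    if (refit$logLik > fit$logLik) fit <- refit
  }
  sols <- fit$solutions$random$animal
  structure(list(vc = fit, vc_rm = rm_fit,
                 genetic = fit$components$animal,
                 sigma2_pe = fit$components$pe,
                 sigma2_hy = fit$components$herd_year,
                 sigma2_e = fit$sigma2_e,
                 a0 = sols[, "a0"], a1 = sols[, "a1"],
                 f = f, groups = groups,
                 logLik_rnm = fit$logLik,
                 logLik_rm = if (fit_rm) rm_fit$logLik else NA_real_,
                 kinship_kind = kinship$kind),
            class = "rnm_fit")
}

#' @export
print.rnm_fit <- function(x, ...) {
  g <- x$genetic
  cat(sprintf("Reaction norm fit (%s)\n", x$kinship_kind))
  cat(sprintf("  var(a0) = %.4g, cov(a0,a1) = %.4g, var(a1) = %.4g, r = %.3f\n",
              g[1, 1], g[1, 2], g[2, 2], intercept_slope_correlation(g)))
  cat(sprintf("  pe = %.4g, herd-year = %.4g, residual = %.4g\n",
              x$sigma2_pe, x$sigma2_hy, x$sigma2_e))
  if (!is.na(x$logLik_rm)) {
    lrt <- lrt_rnm_vs_rm(x$logLik_rm, x$logLik_rnm)
    cat(sprintf("  LRT vs reduced model: D = %.3f, p = %.3g\n",
                lrt$D, lrt$p_value))
  }
  invisible(x)
}

#' Run the full three-step G x E analysis
#'
#' Convenience wrapper: record editing, step 1 (herd effects), step 2
#' (residual groups and weights) and step 3 (reaction norm + reduced
#' model), with either the pedigree relationship matrix (`kinship = "A"`)
#' or the single-step matrix (`kinship = "H"`, which requires genotypes).
#'
#' @param pedigree Pedigree `data.frame`.
#' @param phenotypes Raw phenotype `data.frame`.
#' @param genotypes `snp_geno` (or genotype matrix with id rownames) for
#'   `kinship = "H"`; ignored for `"A"`.
#' @param kinship `"A"` or `"H"`.
#' @param genotyped_ids Ids of genotyped animals (default: all rows of the
#'   genotype matrix).
#' @param omega Blending fraction for G.
#' @param rules [edit_rules()].
#' @param gibbs List with `rounds`, `burnin`, `thin`.
#' @param control [reml_control()].
#' @param edit Apply [edit_records()] first (set `FALSE` if already edited).
#' @return A list with the edited `data`, `step1`, `groups`, `rnm`
#'   (class `rnm_fit`) and the kinship inverse used.
#' @export
run_gxe_pipeline <- function(pedigree, phenotypes, genotypes = NULL,
                             kinship = c("A", "H"), genotyped_ids = NULL,
                             omega = 0.2, rules = edit_rules(),
                             gibbs = list(rounds = 20000L, burnin = 5000L,
                                          thin = 10L),
                             control = reml_control(), edit = TRUE) {
  kinship <- match.arg(kinship)
  data <- if (edit) edit_records(phenotypes, rules) else phenotypes
  Kinv <- pipeline_kinship(pedigree, genotypes, kinship, genotyped_ids, omega)
  s1 <- step1_herd_effects(data, Kinv, control = control)
  s2 <- step2_groups_and_weights(data, s1$f, Kinv,
                                 init = list(components = s1$vc$components,
                                             sigma2_e = s1$vc$sigma2_e),
                                 rounds = gibbs$rounds, burnin = gibbs$burnin,
                                 thin = gibbs$thin)
  s3 <- step3_fit_rnm(data, s1$f, s2, Kinv, control = control)
  list(data = data, step1 = s1, groups = s2, rnm = s3, kinship_inv = Kinv)
}

## Build the kinship inverse for the requested mode.
pipeline_kinship <- function(pedigree, genotypes, kinship = "A",
                             genotyped_ids = NULL, omega = 0.2) {
  Ainv <- build_A_inverse(pedigree)
  if (kinship == "A") return(Ainv)
  if (is.null(genotypes))
    stop("kinship = 'H' requires genotypes")
  G <- if (inherits(genotypes, "snp_geno")) genotypes$genotypes else genotypes
  if (is.null(genotyped_ids)) genotyped_ids <- rownames(G)
  G <- G[as.character(genotyped_ids), , drop = FALSE]
  A <- build_A(pedigree)
  A22 <- subset_A22(A, genotyped_ids)
  G0 <- build_G0(G)
  Gb <- blend_G(G0, A22, omega)
  Ga <- adjust_G_to_A22(Gb, A22)
  build_H_inverse(Ainv, Ga, A22, genotyped_ids)
}
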