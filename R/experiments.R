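## Simulation-study replicates: self-contained experiments used to
## validate the three-step reaction norm machinery on data with known
## truth. Each function runs one seeded replicate of one study design and
## returns the quantities the study tracks. The designs (population sizes,
## herd counts, chain lengths) are fixed here so that the test suite and
## the acceptance script run the same experiments.

#' One replicate of the variance-component recovery study
#'
#' Simulates the default population (2,000 animals, 50 herds, genetic
#' intercept/slope (co)variances 1.0 / -0.3 / 0.2, five residual-variance
#' groups), runs record editing and all three steps, and compares each
#' REML component of the reaction norm model with the generating truth on
#' the scale of its asymptotic standard error.
#'
#' @param seed Replicate seed.
#' @param gibbs Chain settings for step 2.
#' @return A list with `estimates`, `se`, `z` (signed errors in SE units),
#'   `within3` (per component), `weights_identity_ok` (the weighting
#'   preserves the record-weighted mean residual variance), `weights`,
#'   `fit` and `groups`.
#' @export
gxe_recovery_replicate <- function(seed,
                                   gibbs = list(rounds = 6000L,
                                                burnin = 1500L, thin = 5L)) {
  set.seed(seed)
  cfg <- sim_config(seed = seed)
  sim <- simulate_gxe_data(cfg)
  data <- edit_records(sim$phenotypes, edit_rules(herd_year_min = 5))
  Ainv <- build_A_inverse(sim$pedigree)
  s1 <- step1_herd_effects(data, Ainv)
  s2 <- step2_groups_and_weights(data, s1$f, Ainv,
                                 init = list(components = s1$vc$components,
                                             sigma2_e = s1$vc$sigma2_e),
                                 rounds = gibbs$rounds, burnin = gibbs$burnin,
                                 thin = gibbs$thin)
  s3 <- step3_fit_rnm(data, s1$f, s2, Ainv, fit_rm = FALSE)
  truth <- c(animal_v0 = cfg$sigma2_a0, animal_c01 = cfg$sigma_a01,
             animal_v1 = cfg$sigma2_a1, pe = cfg$sigma2_pe,
             herd_year = cfg$sigma2_hy)
  g <- s3$genetic
  est <- c(animal_v0 = g[1, 1], animal_c01 = g[1, 2], animal_v1 = g[2, 2],
           pe = s3$sigma2_pe, herd_year = s3$sigma2_hy)
  se <- s3$vc$se[names(truth)]
  z <- (est - truth) / se
  idw <- abs(sum(s2$n * s2$sigma2_e * s2$weights) / sum(s2$n) -
               sum(s2$n * s2$sigma2_e) / sum(s2$n)) < 1e-8
  list(estimates = est, se = se, z = z, within3 = abs(z) <= 3,
       weights_identity_ok = idw, weights = s2$weights,
       fit = s3, groups = s2)
}

#' One replicate of the likelihood-ratio-test calibration study
#'
#' Simulates a moderate population (about 930 animals, 25 herds,
#' homoskedastic residuals) with or without a genetic slope, runs steps 1
#' and 3 with unit residual weights, and returns the mixture chi-square
#' p-value of the reaction norm against the reduced model.
#'
#' @param seed Replicate seed.
#' @param sigma2_a1 Simulated slope variance (0 for the null).
#' @param sigma_a01 Simulated intercept-slope covariance.
#' @return List with `p_value`, `D` and the `rnm_fit`.
#' @export
lrt_replicate <- function(seed, sigma2_a1 = 0.2,
                          sigma_a01 = if (sigma2_a1 > 0) -0.3 else 0) {
  set.seed(seed)
  cfg <- sim_config(n_founders = 500, n_generations = 2,
                    n_sires_per_gen = 12, n_dams_per_sire = 18,
                    n_snps = 100, n_herds = 25,
                    residual_group_sigmas = rep(1, 5),
                    sigma2_a1 = sigma2_a1, sigma_a01 = sigma_a01,
                    seed = seed)
  sim <- simulate_gxe_data(cfg)
  data <- edit_records(sim$phenotypes, edit_rules(herd_year_min = 5))
  Ainv <- build_A_inverse(sim$pedigree)
  s1 <- step1_herd_effects(data, Ainv)
  s3 <- step3_fit_rnm(data, s1$f, NULL, Ainv)
  lrt <- lrt_rnm_vs_rm(s3$logLik_rm, s3$logLik_rnm)
  list(p_value = lrt$p_value, D = lrt$D, fit = s3)
}

#' One replicate of the single-step GWAS power study
#'
#' Simulates 2,000 SNPs on 10 chromosomes with 300 genotyped sires and a
#' single major slope QTL carrying half of the slope variance, runs the
#' iterative weighted single-step GWAS, and reports whether the QTL's
#' window ranks in the top 10 slope windows, plus the worst back-solve
#' projection error across iterations (on mean-centred breeding values).
#'
#' @param seed Replicate seed.
#' @param n_iter ssGWAS iterations.
#' @return List with `hit`, `qtl_windows`, `top10`, `projection_err`,
#'   `gwas` and the simulated `truth`.
#' @export
ssgwas_replicate <- function(seed, n_iter = 3L) {
  set.seed(seed)
  cfg <- sim_config(n_founders = 1300, n_generations = 3,
                    n_sires_per_gen = 100, n_dams_per_sire = 6,
                    n_snps = 2000, n_chromosomes = 10, n_herds = 40,
                    n_slope_qtl = 1, seed = seed)
  sim <- simulate_gxe_data(cfg)
  data <- edit_records(sim$phenotypes, edit_rules(herd_year_min = 5))
  ped <- sim$pedigree
  sires <- sort(unique(ped$sire[ped$sire != 0]))
  Ainv <- build_A_inverse(ped)
  s1 <- step1_herd_effects(data, Ainv)
  ## estimate the RNM components once with the identity-weight H (warm
  ## start from step 1); the ssGWAS loop then only refreshes BLUPs
  Hinv <- pipeline_kinship(ped, sim$genotypes, "H", genotyped_ids = sires)
  va <- as.numeric(s1$vc$components$animal)
  vf <- max(stats::var(unname(s1$f[as.character(data$herd)])), 1e-8)
  init <- list(components = list(
    animal = matrix(c(va, 0, 0, 0.2 * va / vf), 2, 2),
    herd_year = s1$vc$components$herd_year,
    pe = s1$vc$components$pe), sigma2_e = s1$vc$sigma2_e)
  fitH <- step3_fit_rnm(data, s1$f, NULL, Hinv, fit_rm = FALSE,
                        init = init,
                        control = reml_control(tol_param = 1e-6,
                                               tol_grad = 1e-4,
                                               max_iter = 30))
  gwas <- run_ssgwas(data, ped, sim$genotypes, s1$f, groups = NULL,
                     genotyped_ids = sires, vc = fitH$vc, n_iter = n_iter)
  ## projection identity at every iteration, on centred GEBVs
  cg <- center_genotypes(sim$genotypes$genotypes[as.character(sires), ,
                                                 drop = FALSE])
  perr <- max(vapply(gwas$iterations, function(it) {
    ac <- it$a_hat - mean(it$a_hat)
    max(abs(as.numeric(cg$Z %*% it$u) - ac))
  }, numeric(1)))
  ## windows holding the simulated slope QTL (indices into kept markers)
  qtl <- sim$truth$qtl_indices
  kept_pos <- match(qtl, gwas$marker_index)
  win_of <- vapply(kept_pos, function(k) {
    if (is.na(k)) return(NA_integer_)
    gwas$windows$window[gwas$windows$first <= k & gwas$windows$last >= k]
  }, integer(1))
  slope_order <- gwas$windows$window[order(-gwas$windows$pct_var_slope)]
  top10 <- slope_order[1:10]
  strongest <- which.max(abs(sim$truth$snp_effects[qtl, 2]))
  list(hit = win_of[strongest] %in% top10,
       qtl_windows = win_of, top10 = top10,
       qtl_rank = match(win_of[strongest], slope_order),
       projection_err = perr, gwas = gwas, truth = sim$truth)
}

#' One replicate of the forward-prediction validation study
#'
#' Simulates about 1,200 animals (50 sires, all genotyped along with the
#' other males), holds out the youngest 20% of sires with daughters,
#' fits the reaction norm model on the training records with the pedigree
#' (A) and the single-step (H) relationship matrix, computes daughter
#' yield deviations for the validation sires from their held-out
#' daughters' records, and returns the two validation accuracies
#' cor(DYD, prediction).
#'
#' @param seed Replicate seed.
#' @return List with `accuracy` (named A/H), `n_validation`, and the fits.
#' @export
accuracy_replicate <- function(seed) {
  set.seed(seed)
  cfg <- sim_config(n_founders = 600, n_generations = 2,
                    n_sires_per_gen = 25, n_dams_per_sire = 12,
                    n_snps = 800, n_herds = 20, seed = seed)
  sim <- simulate_gxe_data(cfg)
  ped <- sim$pedigree
  data <- edit_records(sim$phenotypes, edit_rules(herd_year_min = 5))
  split <- validation_split(ped, data, fraction = 0.2)
  train <- split$training_data
  sires <- sort(unique(ped$sire[ped$sire != 0]))
  Ainv <- build_A_inverse(ped)
  s1 <- step1_herd_effects(train, Ainv)
  fitA <- step3_fit_rnm(train, s1$f, NULL, Ainv, fit_rm = FALSE)
  Hinv <- pipeline_kinship(ped, sim$genotypes, "H", genotyped_ids = sires)
  fitH <- step3_fit_rnm(train, s1$f, NULL, Hinv, fit_rm = FALSE)
  ## DYD over the held-out daughters, adjusted with the training A fit
  sire_of <- stats::setNames(ped$sire, ped$id)
  val_data <- data[sire_of[as.character(data$animal)] %in% split$validation, ,
                   drop = FALSE]
  dyd <- compute_dyd(val_data, fitA, ped, min_daughters = 5)
  fbar <- mean_daughter_eg(split$validation, ped, data, s1$f)
  ids <- as.character(split$validation)
  predA <- stats::setNames(combine_ebv(fitA$a0[ids], fitA$a1[ids], fbar[ids]),
                           ids)
  predH <- stats::setNames(combine_ebv(fitH$a0[ids], fitH$a1[ids], fbar[ids]),
                           ids)
  acc <- c(A = validation_accuracy(predA, dyd, split$validation),
           H = validation_accuracy(predH, dyd, split$validation))
  list(accuracy = acc, n_validation = length(split$validation),
       fitA = fitA, fitH = fitH, dyd = dyd)
}
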