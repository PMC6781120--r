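#' Configuration for the synthetic G x E data generator
#'
#' Bundles every knob of the generator: pedigree design, marker panel,
#' herd structure, the 2x2 genetic (co)variance of reaction-norm intercept
#' and slope, non-genetic variances, group-wise residual variances and
#' censoring. Defaults describe a moderate multi-generation half-sib cattle
#' population with a unit-scale fertility-like trait.
#'
#' @param n_founders Number of founder animals (generation 0, unknown parents).
#' @param n_generations Number of offspring generations to simulate.
#' @param n_sires_per_gen Sires sampled per generation; each founds a paternal
#'   half-sib family.
#' @param n_dams_per_sire Dams mated to each sire (one offspring per mating).
#' @param n_snps Number of biallelic markers.
#' @param n_chromosomes Chromosomes the markers are spread over.
#' @param n_herds Number of herds phenotyped animals are assigned to.
#' @param herd_effect_sd Standard deviation of the true herd effects
#'   (trait units); herd effects act as the environmental gradient.
#' @param sigma2_a0,sigma2_a1,sigma_a01 Genetic variance of the intercept,
#'   of the slope, and their covariance. The 2x2 matrix must be positive
#'   semi-definite.
#' @param sigma2_pe Permanent environmental variance.
#' @param sigma2_hy Herd-year variance.
#' @param residual_group_sigmas Residual variances of the five herd groups
#'   (ordered from the lowest to the highest herd-effect group).
#' @param n_slope_qtl Number of markers given large slope effects; jointly
#'   they account for half of the slope variance, split equally.
#' @param censor_rate Probability that a record is flagged right-censored.
#' @param seed Integer seed; identical seeds give byte-identical output.
#'
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_founders = 800L, n_generations = 3L,
                       n_sires_per_gen = 20L, n_dams_per_sire = 20L,
                       n_snps = 2000L, n_chromosomes = 10L,
                       n_herds = 50L, herd_effect_sd = 1,
                       sigma2_a0 = 1.0, sigma2_a1 = 0.2, sigma_a01 = -0.3,
                       sigma2_pe = 0.3, sigma2_hy = 0.2,
                       residual_group_sigmas = c(0.8, 0.9, 1.0, 1.1, 1.2),
                       n_slope_qtl = 5L, censor_rate = 0.05, seed = 1L) {
  cfg <- list(n_founders = as.integer(n_founders),
              n_generations = as.integer(n_generations),
              n_sires_per_gen = as.integer(n_sires_per_gen),
              n_dams_per_sire = as.integer(n_dams_per_sire),
              n_snps = as.integer(n_snps),
              n_chromosomes = as.integer(n_chromosomes),
              n_herds = as.integer(n_herds),
              herd_effect_sd = herd_effect_sd,
              sigma2_a0 = sigma2_a0, sigma2_a1 = sigma2_a1,
              sigma_a01 = sigma_a01,
              sigma2_pe = sigma2_pe, sigma2_hy = sigma2_hy,
              residual_group_sigmas = residual_group_sigmas,
              n_slope_qtl = as.integer(n_slope_qtl),
              censor_rate = censor_rate,
              seed = as.integer(seed))
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(cfg$n_founders >= 1, cfg$n_generations >= 0,
            cfg$n_snps >= 1, cfg$n_chromosomes >= 1, cfg$n_herds >= 1,
            cfg$herd_effect_sd >= 0,
            all(cfg$residual_group_sigmas > 0),
            cfg$censor_rate >= 0, cfg$censor_rate < 1,
            cfg$n_slope_qtl >= 0)
  if (cfg$n_generations > 0 && cfg$n_dams_per_sire < 1)
    stop("impossible mating structure: n_dams_per_sire must be >= 1")
  if (cfg$n_generations > 0 && cfg$n_sires_per_gen < 1)
    stop("impossible mating structure: n_sires_per_gen must be >= 1")
  S <- genetic_cov_matrix(cfg)
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-10 * max(abs(ev), 1))
    stop("genetic (co)variance matrix of (intercept, slope) is not positive semi-definite")
  invisible(cfg)
}

genetic_cov_matrix <- function(cfg) {
  matrix(c(cfg$sigma2_a0, cfg$sigma_a01, cfg$sigma_a01, cfg$sigma2_a1), 2, 2)
}

#' Simulate a multi-generation half-sib pedigree
#'
#' Founders have unknown parents (coded 0). Each later generation mates
#' `n_sires_per_gen` sires (drawn from the males of the previous generation)
#' with `n_dams_per_sire` dams each (drawn without replacement, within a
#' generation, from all earlier females), one offspring per mating, so each
#' sire founds a paternal half-sib family. Animals are numbered 1..n in
#' birth order, so every parent id precedes its offspring's id, and
#' birthdates (days) increase with generation.
#'
#' @param cfg A [sim_config()].
#' @return A `data.frame` with columns `id`, `sire`, `dam`, `birthdate`,
#'   `sex` ("M"/"F") and `generation`.
#' @export
simulate_pedigree <- function(cfg) {
  validate_sim_config(cfg)
  set.seed(cfg$seed)
  n0 <- cfg$n_founders
  id <- seq_len(n0)
  sex <- sample(rep(c("M", "F"), length.out = n0))   # exactly balanced
  ped <- data.frame(id = id, sire = 0L, dam = 0L,
                    birthdate = seq_len(n0),   # distinct days within gen 0
                    sex = sex, generation = 0L,
                    stringsAsFactors = FALSE)
  if (cfg$n_generations == 0L) return(ped)
  for (g in seq_len(cfg$n_generations)) {
    prev_males <- ped$id[ped$sex == "M" & ped$generation == g - 1L]
    if (length(prev_males) < cfg$n_sires_per_gen)
      prev_males <- ped$id[ped$sex == "M"]       # fall back to all males
    if (length(prev_males) < cfg$n_sires_per_gen)
      stop("not enough males to draw ", cfg$n_sires_per_gen, " sires in generation ", g)
    sires <- sample(prev_males, cfg$n_sires_per_gen)
    females <- ped$id[ped$sex == "F"]
    n_dams <- cfg$n_sires_per_gen * cfg$n_dams_per_sire
    if (length(females) < n_dams)
      stop("not enough females to draw ", n_dams, " dams in generation ", g,
           " (have ", length(females), ")")
    dams <- sample(females, n_dams)
    n_off <- n_dams
    off_id <- max(ped$id) + seq_len(n_off)
    ped <- rbind(ped, data.frame(
      id = off_id,
      sire = rep(sires, each = cfg$n_dams_per_sire),
      dam = dams,
      birthdate = 365L * g + seq_len(n_off),
      sex = sample(rep(c("M", "F"), length.out = n_off)),
      generation = g, stringsAsFactors = FALSE))
  }
  rownames(ped) <- NULL
  ped
}

check_pedigree <- function(ped) {
  stopifnot(all(c("id", "sire", "dam") %in% names(ped)))
  n <- nrow(ped)
  if (anyDuplicated(ped$id)) stop("duplicated animal ids in pedigree")
  idx <- match(ped$sire, ped$id)   # NA for unknown (0)
  jdx <- match(ped$dam, ped$id)
  known_s <- !is.na(idx)
  known_d <- !is.na(jdx)
  if (any(idx[known_s] >= seq_len(n)[known_s]) ||
      any(jdx[known_d] >= seq_len(n)[known_d]))
    stop("pedigree not topologically sorted: a parent appears at or after its offspring")
  invisible(list(sire_idx = ifelse(known_s, idx, 0L),
                 dam_idx = ifelse(known_d, jdx, 0L)))
}

#' Simulate SNP genotypes by gene dropping
#'
#' Founder allele frequencies are drawn from Uniform(0.05, 0.95) and founder
#' genotypes from Hardy-Weinberg proportions; each offspring receives one
#' allele from each parent by Mendelian sampling, independently per marker.
#' Markers are placed evenly across chromosomes at 50 kb spacing.
#'
#' @param ped Pedigree from [simulate_pedigree()].
#' @param cfg A [sim_config()].
#' @return An object of class `snp_geno`: list with `genotypes` (animals x
#'   markers matrix of 0/1/2 allele counts, rownames = animal ids), `map`
#'   (marker, chrom, pos) and `founder_freq`.
#' @export
simulate_genotypes <- function(ped, cfg) {
  check_pedigree(ped)
  set.seed(cfg$seed + 1L)
  m <- cfg$n_snps
  n <- nrow(ped)
  p <- runif(m, 0.05, 0.95)
  G <- matrix(0L, n, m, dimnames = list(ped$id, NULL))
  sidx <- match(ped$sire, ped$id)
  didx <- match(ped$dam, ped$id)
  for (i in seq_len(n)) {
    if (is.na(sidx[i]) || is.na(didx[i])) {
      G[i, ] <- rbinom(m, 2L, p)
    } else {
      G[i, ] <- rbinom(m, 1L, G[sidx[i], ] / 2) + rbinom(m, 1L, G[didx[i], ] / 2)
    }
  }
  per_chr <- ceiling(m / cfg$n_chromosomes)
  chrom <- rep(seq_len(cfg$n_chromosomes), each = per_chr)[seq_len(m)]
  pos <- (sequence(rle(chrom)$lengths)) * 50000L
  structure(list(genotypes = G,
                 map = data.frame(marker = paste0("snp", seq_len(m)),
                                  chrom = chrom, pos = pos),
                 founder_freq = p),
            class = "snp_geno")
}

## Age classes for age at first insemination (days), five groups.
AGE_CLASS_BREAKS <- c(270, 420, 445, 470, 500, 900)

#' Simulate reaction-norm phenotypes with known truth
#'
#' True breeding values (intercept `a0`, slope `a1`) are built from per-SNP
#' bivariate effects on centred genotypes and rescaled so their empirical
#' 2x2 (co)variance in the founder population matches the configuration
#' exactly; `n_slope_qtl` markers carry large slope effects that jointly
#' account for half of the slope variance. Every non-founder female receives
#' one record per parity (1-3 parities), in a randomly assigned herd, with
#' `y = mu + parity + year + month + age class + f_herd + a0 + a1 * f_herd +
#' hy + pe + e`, where the residual is drawn from one of five group-wise
#' variances determined by record-weighted quantiles (10/30/70/90%) of the
#' true herd effects. Records are flagged censored with probability
#' `censor_rate`; the stored value is the uncensored one (penalties are the
#' business of [edit_records()]).
#'
#' @param ped Pedigree from [simulate_pedigree()].
#' @param geno Genotypes from [simulate_genotypes()].
#' @param cfg A [sim_config()].
#' @return A list with `phenotypes` (a `data.frame` with columns `animal`,
#'   `trait`, `value`, `censored`, `herd`, `herd_year`, `parity`, `year`,
#'   `month`, `age_days`, `dam`) and `truth` (class `sim_truth`).
#' @export
simulate_phenotypes <- function(ped, geno, cfg) {
  check_pedigree(ped)
  validate_sim_config(cfg)
  set.seed(cfg$seed + 2L)
  n <- nrow(ped)
  G <- geno$genotypes
  m <- ncol(G)
  p <- colMeans(G) / 2
  het <- 2 * p * (1 - p)
  Zc <- sweep(G, 2, 2 * p)

  S <- genetic_cov_matrix(cfg)
  degenerate_slope <- cfg$sigma2_a1 <= 0 && cfg$sigma_a01 == 0
  qtl_indices <- integer(0)
  denom <- sum(het)
  if (degenerate_slope) {
    alpha <- cbind(rnorm(m, 0, sqrt(max(cfg$sigma2_a0, 0) / denom)), 0)
  } else {
    ch <- chol(S + diag(1e-12, 2))
    alpha <- matrix(rnorm(2 * m), m, 2) %*% (ch / sqrt(denom))
    if (cfg$n_slope_qtl > 0 && cfg$sigma2_a1 > 0) {
      cand <- which(p > 0.2 & p < 0.8)
      qtl_indices <- sort(sample(cand, min(cfg$n_slope_qtl, length(cand))))
      # QTL take half the slope variance, split equally; polygenic half
      # kept. QTL are pleiotropic: each also carries the intercept effect
      # implied by regressing intercept on slope (sigma_a01 / sigma2_a1),
      # mirroring the negative intercept-slope correlation of fertility
      # reaction norms (shared top windows, opposite directions).
      alpha[, 2] <- alpha[, 2] * sqrt(0.5)
      qv <- 0.5 * cfg$sigma2_a1 / length(qtl_indices)
      qeff <- sample(c(-1, 1), length(qtl_indices), replace = TRUE) *
        sqrt(qv / het[qtl_indices])
      alpha[qtl_indices, 2] <- alpha[qtl_indices, 2] + qeff
      alpha[qtl_indices, 1] <- alpha[qtl_indices, 1] +
        (cfg$sigma_a01 / cfg$sigma2_a1) * qeff
    }
  }
  a <- Zc %*% alpha                       # n x 2, pre-scaling
  founders <- which(ped$sire == 0 & ped$dam == 0)
  if (degenerate_slope) {
    v0 <- stats::var(a[founders, 1])
    sc <- if (v0 > 0) sqrt(cfg$sigma2_a0 / v0) else 0
    alpha[, 1] <- alpha[, 1] * sc
  } else {
    emp <- stats::cov(a[founders, , drop = FALSE]) + diag(1e-12, 2)
    ## lower-triangular factors: M emp M' = S exactly
    M <- t(chol(S + diag(1e-12, 2))) %*% solve(t(chol(emp)))
    alpha <- alpha %*% t(M)
  }
  a <- Zc %*% alpha
  true_a0 <- stats::setNames(a[, 1], ped$id)
  true_a1 <- stats::setNames(a[, 2], ped$id)

  ## herd structure
  rec_animals <- ped$id[ped$sex == "F" & ped$generation > 0]
  if (length(rec_animals) == 0)
    stop("no non-founder females: nothing to phenotype")
  herd_of <- stats::setNames(sample(cfg$n_herds, length(rec_animals), replace = TRUE),
                             rec_animals)
  f_true <- rnorm(cfg$n_herds, 0, cfg$herd_effect_sd)

  ## records: one per parity, 1..3 parities per animal
  n_par <- sample(1:3, length(rec_animals), replace = TRUE)
  animal <- rep(rec_animals, n_par)
  parity <- sequence(n_par)
  herd <- herd_of[as.character(animal)]
  gen <- ped$generation[match(animal, ped$id)]
  year <- gen + parity                     # calving year index
  month <- sample(1:12, length(animal), replace = TRUE)
  age1 <- stats::setNames(round(runif(length(rec_animals), 300, 850)), rec_animals)
  age_days <- age1[as.character(animal)]

  ## residual groups from record-weighted quantiles of true herd effects
  grp <- eg_groups(f_true, herd)

  ## fixed-effect truths (drawn once, modest scale)
  mu <- 10
  parity_eff <- c(0, 0.3, 0.5)
  year_lev <- sort(unique(year))
  year_eff <- stats::setNames(rnorm(length(year_lev), 0, 0.2), year_lev)
  month_eff <- stats::setNames(rnorm(12, 0, 0.1), 1:12)
  age_class <- cut(age_days, AGE_CLASS_BREAKS, right = FALSE, labels = FALSE)
  age_eff <- stats::setNames(rnorm(5, 0, 0.15), 1:5)

  hy_key <- paste(herd, year, sep = "-")
  hy_lev <- sort(unique(hy_key))
  hy_eff <- stats::setNames(rnorm(length(hy_lev), 0, sqrt(cfg$sigma2_hy)), hy_lev)
  pe_eff <- stats::setNames(rnorm(length(rec_animals), 0, sqrt(cfg$sigma2_pe)),
                            rec_animals)
  e_sd <- sqrt(cfg$residual_group_sigmas[grp$herd_group[herd]])
  e <- rnorm(length(animal), 0, e_sd)

  y <- mu + parity_eff[parity] + year_eff[as.character(year)] +
    month_eff[as.character(month)] + age_eff[as.character(age_class)] +
    f_true[herd] + true_a0[as.character(animal)] +
    true_a1[as.character(animal)] * f_true[herd] +
    hy_eff[hy_key] + pe_eff[as.character(animal)] + e

  censored <- runif(length(animal)) < cfg$censor_rate
  phen <- data.frame(animal = animal, trait = "SIM", value = as.numeric(y),
                     censored = censored, herd = herd, herd_year = hy_key,
                     parity = parity, year = year, month = month,
                     age_days = as.integer(age_days),
                     dam = ped$dam[match(animal, ped$id)],
                     stringsAsFactors = FALSE)
  rownames(phen) <- NULL
  truth <- structure(list(true_a0 = true_a0, true_a1 = true_a1,
                          true_herd_effects = f_true,
                          qtl_indices = qtl_indices,
                          snp_effects = alpha,
                          herd_of = herd_of, pe = pe_eff, hy = hy_eff,
                          herd_group = grp$herd_group,
                          residual_group_sigmas = cfg$residual_group_sigmas),
                     class = "sim_truth")
  list(phenotypes = phen, truth = truth)
}

## Record-weighted quantile grouping of herds by a herd-level value.
## Returns per-herd group index 1..(length(quantiles)+1).
eg_groups <- function(herd_values, record_herds,
                      quantiles = c(0.10, 0.30, 0.70, 0.90)) {
  n_herds <- length(herd_values)
  counts <- tabulate(record_herds, nbins = n_herds)
  ord <- order(herd_values)
  cum <- cumsum(counts[ord])
  mid <- (cum - counts[ord] / 2) / sum(counts)  # midpoint of each herd's mass
  g <- stats::setNames(integer(n_herds), seq_len(n_herds))
  ## a herd belongs to the group the midpoint of its record mass falls in
  g[ord] <- findInterval(mid, quantiles, left.open = TRUE) + 1L
  list(herd_group = g, cuts = quantiles)
}

#' Simulate a complete G x E dataset
#'
#' Runs [simulate_pedigree()], [simulate_genotypes()] and
#' [simulate_phenotypes()] under one configuration.
#'
#' @param cfg A [sim_config()].
#' @return A list with `pedigree`, `genotypes`, `phenotypes`, `truth`
#'   and `config`.
#' @export
simulate_gxe_data <- function(cfg) {
  ped <- simulate_pedigree(cfg)
  geno <- simulate_genotypes(ped, cfg)
  ph <- simulate_phenotypes(ped, geno, cfg)
  list(pedigree = ped, genotypes = geno, phenotypes = ph$phenotypes,
       truth = ph$truth, config = cfg)
}

#' Write simulated data as plain-text files
#'
#' Pedigree as CSV (`id,sire,dam,birthdate,sex`; 0 = unknown parent),
#' genotypes as TSV (one row per individual, columns = markers) with a
#' companion map TSV (`marker,chrom,pos`), phenotypes as CSV.
#'
#' @param sim Output of [simulate_gxe_data()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
write_sim_data <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(pedigree = file.path(dir, "pedigree.csv"),
             genotypes = file.path(dir, "genotypes.tsv"),
             map = file.path(dir, "map.tsv"),
             phenotypes = file.path(dir, "phenotypes.csv"))
  utils::write.csv(sim$pedigree[, c("id", "sire", "dam", "birthdate", "sex")],
                   paths["pedigree"], row.names = FALSE, quote = FALSE)
  gt <- data.frame(id = rownames(sim$genotypes$genotypes),
                   sim$genotypes$genotypes, check.names = FALSE)
  names(gt) <- c("id", sim$genotypes$map$marker)
  utils::write.table(gt, paths["genotypes"], sep = "\t",
                     row.names = FALSE, quote = FALSE)
  utils::write.table(sim$genotypes$map, paths["map"], sep = "\t",
                     row.names = FALSE, quote = FALSE)
  utils::write.csv(sim$phenotypes, paths["phenotypes"],
                   row.names = FALSE, quote = FALSE)
  invisible(paths)
}
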