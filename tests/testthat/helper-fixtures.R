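## Shared fixtures, built once per test run.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixtures))
    assign(key, force(expr), envir = .fixtures)
  get(key, envir = .fixtures)
}

## A small population: 540 animals, 12 herds, 400 SNPs.
small_sim <- function() memo("small_sim", {
  cfg <- sim_config(n_founders = 300, n_generations = 2,
                    n_sires_per_gen = 10, n_dams_per_sire = 12,
                    n_snps = 400, n_chromosomes = 4, n_herds = 12,
                    seed = 42)
  sim <- simulate_gxe_data(cfg)
  sim$Ainv <- build_A_inverse(sim$pedigree)
  sim$A <- build_A(sim$pedigree)
  sim
})

## Editing rules scaled to the generator's record density (about 25
## records per herd): keep the mechanics, lower the herd-year minimum.
sim_rules <- function() edit_rules(herd_year_min = 5L)

## pedigree: unrelated sire (1), dam (2), offspring (3)
trio_pedigree <- function() {
  data.frame(id = 1:3, sire = c(0L, 0L, 1L), dam = c(0L, 0L, 2L),
             birthdate = 1:3, sex = c("M", "F", "F"))
}

## sire (1) x his own daughter (3): offspring (4) is inbred, F = 0.25
inbred_pedigree <- function() {
  data.frame(id = 1:4, sire = c(0L, 0L, 1L, 1L), dam = c(0L, 0L, 2L, 3L),
             birthdate = 1:4, sex = c("M", "F", "F", "F"))
}

## tiny phenotype table for editing tests
toy_records <- function(trait, value, censored = FALSE, herd = 1L,
                        year = 2011L, parity = 1L, age_days = 400L,
                        animal = NULL) {
  n <- max(length(trait), length(value), length(censored), length(herd),
           length(year), length(parity), length(age_days))
  if (is.null(animal)) animal <- seq_len(n)
  data.frame(animal = animal, trait = trait, value = value,
             censored = censored, herd = herd,
             herd_year = paste(herd, year, sep = "-"),
             parity = parity, year = year, month = 1L,
             age_days = age_days, dam = 0L)
}

## step-1 + step-3 fits on the small population (pedigree kinship)
small_fit <- function() memo("small_fit", {
  sim <- small_sim()
  data <- edit_records(sim$phenotypes, sim_rules())
  s1 <- step1_herd_effects(data, sim$Ainv)
  s3 <- step3_fit_rnm(data, s1$f, NULL, sim$Ainv)
  list(data = data, s1 = s1, s3 = s3)
})
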