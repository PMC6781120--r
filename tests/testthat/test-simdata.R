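test_that("pedigree simulation respects the mating design", {
  cfg0 <- sim_config(n_founders = 10, n_generations = 0, seed = 1)
  ped0 <- simulate_pedigree(cfg0)
  expect_equal(nrow(ped0), 10)
  expect_true(all(ped0$sire == 0 & ped0$dam == 0))

  cfg <- sim_config(n_founders = 150, n_generations = 3,
                    n_sires_per_gen = 5, n_dams_per_sire = 10, seed = 2)
  ped <- simulate_pedigree(cfg)
  expect_equal(as.integer(table(ped$generation)), c(150, 50, 50, 50))
  ## paternal half-sib families of the designed size
  off <- ped[ped$generation == 1, ]
  expect_true(all(table(off$sire) == 10))
  ## birthdates increase with generation
  expect_true(all(diff(ped$birthdate[order(ped$id)]) > 0 |
                    diff(ped$generation[order(ped$id)]) >= 0))
  agg <- tapply(ped$birthdate, ped$generation, min)
  expect_true(all(diff(agg) > 0))
})

test_that("pedigrees are topologically sorted and reject bad designs", {
  for (s in 1:3) {
    ped <- simulate_pedigree(sim_config(n_founders = 80, n_generations = 2,
                                        n_sires_per_gen = 4,
                                        n_dams_per_sire = 8, seed = s))
    i <- seq_len(nrow(ped))
    si <- match(ped$sire, ped$id)
    di <- match(ped$dam, ped$id)
    expect_true(all(si[!is.na(si)] < i[!is.na(si)]))
    expect_true(all(di[!is.na(di)] < i[!is.na(di)]))
  }
  expect_error(sim_config(n_dams_per_sire = 0), "impossible mating")
})

test_that("identical seed gives byte-identical simulated data", {
  cfg <- sim_config(n_founders = 100, n_generations = 1,
                    n_sires_per_gen = 4, n_dams_per_sire = 6,
                    n_snps = 50, seed = 9)
  s1 <- simulate_gxe_data(cfg)
  s2 <- simulate_gxe_data(cfg)
  expect_identical(s1$pedigree, s2$pedigree)
  expect_identical(s1$genotypes, s2$genotypes)
  expect_identical(s1$phenotypes, s2$phenotypes)
})

test_that("gene dropping is Mendelian and matches pedigree relationships", {
  sim <- small_sim()
  G <- sim$genotypes$genotypes
  ped <- sim$pedigree
  ## both parents homozygous 0 -> offspring 0; both 2 -> offspring 2
  off <- which(ped$sire != 0)
  si <- match(ped$sire[off], ped$id); di <- match(ped$dam[off], ped$id)
  for (k in sample(off, 20)) {
    i <- which(off == k)
    zz <- G[si[i], ] == 0 & G[di[i], ] == 0
    expect_true(all(G[k, zz] == 0))
    tt <- G[si[i], ] == 2 & G[di[i], ] == 2
    expect_true(all(G[k, tt] == 2))
  }
  ## genotypes in 0/1/2
  expect_true(all(G %in% 0:2))
  ## markers spread over the requested chromosomes
  expect_equal(sort(unique(sim$genotypes$map$chrom)), 1:4)
})

test_that("genomic relationships track pedigree relationships", {
  ## one replicate with >= 2000 markers, as a structural check of the
  ## gene-dropping: correlation of off-diagonal G0 and A among descendants
  cfg <- sim_config(n_founders = 120, n_generations = 2,
                    n_sires_per_gen = 6, n_dams_per_sire = 10,
                    n_snps = 2000, seed = 31)
  sim <- simulate_gxe_data(cfg)
  desc <- as.character(sim$pedigree$id[sim$pedigree$generation > 0])
  A <- build_A(sim$pedigree)
  G0 <- build_G0(sim$genotypes$genotypes[desc, ])
  A22 <- subset_A22(A, desc)
  lo <- lower.tri(G0$values)
  expect_gt(cor(G0$values[lo], A22$values[lo]), 0.8)
})

test_that("true breeding values realize the configured (co)variances", {
  ## law-of-large-numbers check at >= 5000 animals, one fixed replicate
  cfg <- sim_config(n_founders = 2600, n_generations = 2,
                    n_sires_per_gen = 30, n_dams_per_sire = 40,
                    n_snps = 1000, seed = 77)
  sim <- simulate_gxe_data(cfg)
  expect_gte(nrow(sim$pedigree), 5000)
  V <- cov(cbind(sim$truth$true_a0, sim$truth$true_a1))
  expect_lt(abs(V[1, 1] - 1.0) / 1.0, 0.10)
  expect_lt(abs(V[2, 2] - 0.2) / 0.2, 0.10)
  expect_lt(abs(V[1, 2] - (-0.3)) / 0.3, 0.10)
  ## founders match exactly by construction
  f <- sim$pedigree$generation == 0
  Vf <- cov(cbind(sim$truth$true_a0[f], sim$truth$true_a1[f]))
  expect_equal(unname(Vf), matrix(c(1, -0.3, -0.3, 0.2), 2), tolerance = 1e-8)
})

test_that("degenerate configurations collapse as expected", {
  cfg <- sim_config(n_founders = 100, n_generations = 1,
                    n_sires_per_gen = 4, n_dams_per_sire = 6, n_snps = 100,
                    sigma2_a1 = 0, sigma_a01 = 0, censor_rate = 0, seed = 5)
  sim <- simulate_gxe_data(cfg)
  expect_true(all(sim$truth$true_a1 == 0))
  expect_true(all(!sim$phenotypes$censored))
  expect_length(sim$truth$qtl_indices, 0)
  ## non-PSD genetic covariance rejected
  expect_error(sim_config(sigma2_a0 = 1, sigma2_a1 = 0.1, sigma_a01 = 0.9),
               "positive semi-definite")
})

test_that("phenotype records carry the expected structure", {
  sim <- small_sim()
  ph <- sim$phenotypes
  expect_true(all(c("animal", "trait", "value", "censored", "herd",
                    "herd_year", "parity", "year", "month", "age_days",
                    "dam") %in% names(ph)))
  expect_true(all(ph$parity %in% 1:3))
  ## one record per animal per parity
  expect_false(anyDuplicated(ph[, c("animal", "parity")]) > 0)
  ## only non-founder females get records
  ped <- sim$pedigree
  rec <- unique(ph$animal)
  expect_true(all(ped$sex[match(rec, ped$id)] == "F"))
  expect_true(all(ped$generation[match(rec, ped$id)] > 0))
})

test_that("simulated files round-trip as plain text", {
  sim <- small_sim()
  dir <- tempfile()
  paths <- write_sim_data(sim, dir)
  ped <- read.csv(paths["pedigree"])
  expect_equal(nrow(ped), nrow(sim$pedigree))
  gt <- read.delim(paths["genotypes"], check.names = FALSE)
  expect_equal(unname(as.matrix(gt[, -1])),
               unname(sim$genotypes$genotypes))
  unlink(dir, recursive = TRUE)
})
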