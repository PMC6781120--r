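test_that("tabular A reproduces textbook relationships", {
  ## unrelated founders -> identity
  ped <- data.frame(id = 1:10, sire = 0L, dam = 0L)
  expect_equal(unname(as.matrix(build_A(ped)$values)), diag(10))
  ## parent-offspring trio
  A <- build_A(trio_pedigree())$values
  expect_equal(A[1, 3], 0.5)
  expect_equal(A[2, 3], 0.5)
  expect_equal(A[3, 3], 1)
  ## sire x daughter mating: F = 0.25, diagonal 1.25
  Ai <- build_A(inbred_pedigree())$values
  expect_equal(Ai[4, 4], 1.25)
  expect_equal(unname(inbreeding(inbred_pedigree())), c(0, 0, 0, 0.25))
})

test_that("sparse A inverse matches the dense inverse, with inbreeding", {
  ped <- small_sim()$pedigree[1:350, ]
  A <- build_A(ped)
  Ainv <- build_A_inverse(ped)
  expect_lt(max(abs(Ainv$values %*% A$values - Matrix::Diagonal(nrow(ped)))),
            1e-8)
  expect_lt(max(abs(as.matrix(Ainv$values) - solve(A$values))), 1e-6)
  ## founders only -> identity
  ped0 <- data.frame(id = 1:5, sire = 0L, dam = 0L)
  expect_equal(unname(as.matrix(build_A_inverse(ped0)$values)), diag(5))
  ## inbred pedigree still inverts exactly
  Ai <- build_A(inbred_pedigree())
  Aiv <- build_A_inverse(inbred_pedigree())
  expect_lt(max(abs(as.matrix(Aiv$values %*% Ai$values) - diag(4))), 1e-12)
})

test_that("A22 subsetting is a consistent permutation-equivariant restriction", {
  sim <- small_sim()
  A <- sim$A
  ids <- as.character(sim$pedigree$id)
  expect_equal(subset_A22(A, ids)$values, as.matrix(A$values))
  one <- subset_A22(A, ids[7])
  expect_equal(unname(one$values[1, 1]), unname(as.matrix(A$values)[7, 7]))
  sub <- sample(ids, 20)
  A22 <- subset_A22(A, sub)
  perm <- sample(seq_along(sub))
  A22p <- subset_A22(A, sub[perm])
  expect_equal(A22p$values, A22$values[perm, perm])
  expect_error(subset_A22(A, "999999"), "unknown ids")
})

test_that("G0 matches its hand-computed definition", {
  geno <- matrix(c(0L, 2L, 2L, 0L), 2, 2, dimnames = list(c("a", "b"), NULL))
  G0 <- build_G0(geno)
  expect_equal(unname(G0$values), matrix(c(2, -2, -2, 2), 2))
  ## linearity in D: doubling weights doubles G0
  G0d <- build_G0(geno, snp_weights(c(2, 2)))
  expect_equal(G0d$values, 2 * G0$values)
  ## swapping allele labels at a marker leaves G0 unchanged
  geno2 <- geno; geno2[, 1] <- 2L - geno2[, 1]
  expect_equal(build_G0(geno2)$values, G0$values)
})

test_that("G0 has unit mean diagonal for HWE founders and is PSD", {
  cfg <- sim_config(n_founders = 200, n_generations = 0, n_snps = 5000,
                    seed = 13)
  ped <- simulate_pedigree(cfg)
  geno <- simulate_genotypes(ped, cfg)
  G0 <- build_G0(geno)
  expect_lt(abs(mean(diag(G0$values)) - 1), 0.1)
  ev <- eigen(G0$values, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), -1e-8)
  ## monomorphic-only genotypes are rejected
  expect_error(build_G0(matrix(2L, 4, 3)), "monomorphic")
})

test_that("blending interpolates between G0 and A22", {
  geno <- matrix(c(0L, 2L, 2L, 0L), 2, 2, dimnames = list(c("a", "b"), NULL))
  G0 <- build_G0(geno)
  A22 <- kinship(diag(2), "A22", c("a", "b"))
  expect_equal(blend_G(G0, A22, 0)$values, G0$values)
  expect_equal(unname(blend_G(G0, A22, 1)$values),
               unname(as.matrix(A22$values)))
  Gb <- blend_G(G0, A22, 0.2)
  expect_equal(unname(Gb$values), matrix(c(1.8, -1.6, -1.6, 1.8), 2))
  expect_equal(Gb$omega, 0.2)
  expect_error(blend_G(G0, A22, 1.5), "omega")
})

test_that("compatibility adjustment matches A22's two moments", {
  sim <- small_sim()
  ids <- as.character(sample(sim$pedigree$id, 40))
  A22 <- subset_A22(sim$A, ids)
  G0 <- build_G0(sim$genotypes$genotypes[ids, ])
  Gb <- blend_G(G0, A22, 0.2)
  Ga <- adjust_G_to_A22(Gb, A22)
  expect_lt(abs(mean(diag(Ga$values)) - mean(diag(A22$values))), 1e-10)
  expect_lt(abs(mean(Ga$values) - mean(A22$values)), 1e-10)
  ## G already compatible -> unchanged
  expect_equal(adjust_G_to_A22(A22mock <- kinship(as.matrix(A22$values),
                                                  "G_blend", ids), A22)$values,
               as.matrix(A22$values))
  ## G = 2 A22 -> beta 0.5, alpha 0
  G2 <- kinship(2 * as.matrix(A22$values), "G_blend", ids)
  expect_equal(adjust_G_to_A22(G2, A22)$values, as.matrix(A22$values),
               tolerance = 1e-12)
})

test_that("H inverse reduces to A inverse in degenerate cases", {
  sim <- small_sim()
  Ainv <- sim$Ainv
  ids <- as.character(sample(sim$pedigree$id, 25))
  A22 <- subset_A22(sim$A, ids)
  ## no genotyped animals
  H0 <- build_H_inverse(Ainv, A22, A22, character(0))
  expect_equal(as.matrix(H0$values), as.matrix(Ainv$values))
  ## G equal to A22: correction vanishes exactly
  A22g <- kinship(as.matrix(A22$values), "G_adj", ids)
  H1 <- build_H_inverse(Ainv, A22g, A22, ids)
  expect_equal(as.matrix(H1$values), as.matrix(Ainv$values))
})

test_that("kinship objects validate their invariants", {
  expect_error(kinship(diag(3), "A", c("1", "2")), "dimensions")
  expect_error(kinship(diag(2), "A", c("1", "1")), "duplicated")
  expect_error(snp_weights(c(1, -1)), "nonnegative")
  K <- kinship(diag(2), "A", c("1", "2"))
  expect_output(print(K), "kinship A")
  ## coordinate export round-trips
  path <- tempfile(fileext = ".tsv")
  write_kinship_coo(small_sim()$Ainv, path)
  coo <- read.delim(path)
  expect_true(all(c("row", "col", "value") %in% names(coo)))
  unlink(path)
})
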