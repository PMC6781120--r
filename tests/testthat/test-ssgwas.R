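test_that("back-solving reproduces hand-computed effects", {
  ## one animal, two markers, centred row (-1, 1)
  Z <- matrix(c(-1, 1), 1, 2)
  eff <- backsolve_snp_effects(Z, a_hat = 3)
  expect_equal(eff$u, c(-1.5, 1.5))
  expect_equal(as.numeric(Z %*% eff$u), 3)
  ## zero breeding values give zero effects
  expect_equal(backsolve_snp_effects(Z, 0)$u, c(0, 0))
  expect_error(backsolve_snp_effects(Z, c(1, 2)), "does not match")
})

test_that("the projection identity holds at full row rank", {
  set.seed(70)
  Z <- matrix(rnorm(50 * 300), 50, 300)
  a <- rnorm(50)
  for (w in list(NULL, snp_weights(runif(300, 0.5, 2)))) {
    eff <- backsolve_snp_effects(Z, a, w)
    expect_lt(max(abs(Z %*% eff$u - a)), 1e-8)
  }
  ## rank-deficient case: identity holds on the projected values
  Zc <- scale(Z, scale = FALSE)       # centred: rank n - 1
  effc <- backsolve_snp_effects(Zc, a)
  expect_lt(max(abs(Zc %*% effc$u - (a - mean(a)))), 1e-8)
})

test_that("SNP re-weighting preserves the implied genetic variance", {
  u <- c(2, 1); p <- c(0.5, 0.5)
  w <- update_snp_weights(u, p)
  expect_equal(w$weights[1] / w$weights[2], 4)  # u^2 ratio at equal p
  het <- 2 * p * (1 - p)
  expect_lt(abs(sum(w$weights * het) - sum(het)), 1e-10)
  ## equal effects and frequencies: equal weights (= 1 after normalisation)
  we <- update_snp_weights(c(1, 1, 1), c(0.3, 0.3, 0.3))
  expect_equal(we$weights, rep(1, 3))
  ## all-zero effects: identity weights with a warning
  expect_warning(w0 <- update_snp_weights(c(0, 0), p), "zero")
  expect_equal(w0$weights, c(1, 1))
  ## zero-effect markers floored, not zeroed
  wf <- update_snp_weights(c(1, 0), p)
  expect_gt(wf$weights[2], 0)
})

test_that("windows partition chromosomes with a merged last window", {
  set.seed(71)
  Z <- matrix(rnorm(30 * 46), 30, 46)
  map <- data.frame(marker = paste0("m", 1:46), chrom = 1, pos = 1:46)
  u <- rnorm(46)
  res <- window_variance_percentages(u, Z, map, sigma2_a = 1, window = 20)
  expect_equal(nrow(res), 2)
  expect_equal(res$size, c(20, 26))
  expect_equal(res$first, c(1, 21))
  expect_equal(res$last, c(20, 46))
  ## a chromosome with fewer than 20 markers is one window
  map2 <- data.frame(marker = paste0("m", 1:46),
                     chrom = rep(c(1, 2), c(34, 12)), pos = c(1:34, 1:12))
  res2 <- window_variance_percentages(u, Z, map2, 1, 20)
  expect_equal(res2$size, c(34, 12))
  ## zero effects explain zero variance
  expect_true(all(window_variance_percentages(u * 0, Z, map, 1)$pct_var == 0))
})

test_that("window percentages match the single-marker oracle and partition", {
  set.seed(72)
  n <- 40; m <- 60
  Z <- scale(matrix(rbinom(n * m, 2, 0.4), n, m), scale = FALSE)
  map <- data.frame(marker = paste0("m", 1:m), chrom = rep(1:2, each = 30),
                    pos = rep(1:30, 2))
  u <- numeric(m); u[7] <- 0.8
  s2 <- 2.5
  res <- window_variance_percentages(u, Z, map, s2, 20)
  expect_equal(res$pct_var[1], 100 * var(Z[, 7]) * 0.8^2 / s2)
  expect_true(all(res$pct_var[-1] == 0))
  ## summed window genetic values reconstruct Z u per individual
  u2 <- rnorm(m)
  tot <- rep(0, n)
  for (k in seq_len(nrow(res))) {
    sel <- res$first[k]:res$last[k]
    tot <- tot + as.numeric(Z[, sel] %*% u2[sel])
  }
  expect_equal(tot, as.numeric(Z %*% u2), tolerance = 1e-12)
  ## within-window marker order is irrelevant
  perm <- c(sample(1:20), 21:m)
  resp <- window_variance_percentages(u2[perm], Z[, perm], map, s2, 20)
  resb <- window_variance_percentages(u2, Z, map, s2, 20)
  expect_equal(resp$pct_var, resb$pct_var, tolerance = 1e-12)
})

test_that("one unweighted iteration equals a plain back-solve", {
  sim <- small_sim()
  fit <- small_fit()
  set.seed(73)
  sires <- unique(sim$pedigree$sire); sires <- sires[sires != 0]
  gw <- run_ssgwas(fit$data, sim$pedigree, sim$genotypes, fit$s1$f,
                   genotyped_ids = sires, vc = fit$s3$vc, n_iter = 1)
  ## the in-loop effects used identity weights
  expect_equal(gw$iterations[[1]]$weights, rep(1, nrow(gw$effects)))
  ## final per-component effects also used identity weights (n_iter = 1)
  cg <- ssrnm:::center_genotypes(sim$genotypes$genotypes[as.character(sires), ])
  rnm <- gw$rnm
  direct <- backsolve_snp_effects(cg$Z, unname(rnm$a0[as.character(sires)]))
  expect_equal(gw$effects$u0, direct$u, tolerance = 1e-10)
  ## projection identity at the loop's breeding values
  fbar <- mean_daughter_eg(sires, sim$pedigree, fit$data, fit$s1$f)
  a_hat <- combine_ebv(rnm$a0[as.character(sires)],
                       rnm$a1[as.character(sires)],
                       fbar[as.character(sires)])
  ## centred Z spans only contrasts: the identity holds on centred GEBVs
  expect_lt(max(abs(cg$Z %*% gw$iterations[[1]]$u -
                      (a_hat - mean(a_hat)))), 1e-8)
})
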