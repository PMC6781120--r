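test_that("breeding values combine linearly along the gradient", {
  expect_equal(combine_ebv(1.2, 0.5, 0), 1.2)
  expect_equal(combine_ebv(1, 0.5, 2), 2)
  ## linear interpolation between a0 and a0 + f a1
  a0 <- 1; a1 <- -0.4; f <- 1.5
  alpha <- seq(0, 1, by = 0.25)
  expect_equal(combine_ebv(a0, a1, alpha * f),
               a0 + alpha * (combine_ebv(a0, a1, f) - a0))
})

## minimal hand-built fit object for DYD contracts
fake_fit <- function(f, fixed = c(`(Intercept)` = 0), hy = numeric(0),
                     pe = numeric(0), a0 = numeric(0), a1 = numeric(0),
                     fixed_cols = character(0)) {
  structure(list(
    vc = list(solutions = list(fixed = fixed,
                               random = list(herd_year = hy, pe = pe)),
              spec = list(fixed = fixed_cols)),
    f = f, a0 = a0, a1 = a1), class = "rnm_fit")
}

test_that("a noiseless daughter record returns its own value as DYD", {
  ped <- trio_pedigree()
  dat <- toy_records("SIM", 3.7, animal = 3)
  fit <- fake_fit(f = c("1" = 0))
  dyd <- compute_dyd(dat, fit, ped, min_daughters = 1)
  expect_equal(dyd$dyd, 3.7)
  expect_equal(dyd$sire, 1)
  ## half the dam's breeding value is subtracted
  fit2 <- fake_fit(f = c("1" = 0), a0 = c("2" = 1), a1 = c("2" = 0))
  expect_equal(compute_dyd(dat, fit2, ped, min_daughters = 1)$dyd, 3.2)
})

test_that("DYD is invariant to a constant shift absorbed by herd effects", {
  ped <- trio_pedigree()
  dat <- toy_records("SIM", 3.7, animal = 3)
  base <- compute_dyd(dat, fake_fit(f = c("1" = 0),
                                    fixed = c(`(Intercept)` = 0, herd1 = 0),
                                    fixed_cols = "herd"), ped,
                      min_daughters = 1)
  dat2 <- dat; dat2$value <- dat2$value + 5
  shift <- compute_dyd(dat2, fake_fit(f = c("1" = 0),
                                      fixed = c(`(Intercept)` = 0, herd1 = 5),
                                      fixed_cols = "herd"), ped,
                       min_daughters = 1)
  expect_equal(base$dyd, shift$dyd)
})

test_that("DYD tracks true transmitting ability on simulated data", {
  ## ~8 sires with ~25 daughters x ~2 records each (>= 50 records/sire)
  cfg <- sim_config(n_founders = 850, n_generations = 1,
                    n_sires_per_gen = 8, n_dams_per_sire = 50,
                    n_snps = 60, n_herds = 8, seed = 61)
  sim <- simulate_gxe_data(cfg)
  Ainv <- build_A_inverse(sim$pedigree)
  data <- edit_records(sim$phenotypes, sim_rules())
  s1 <- step1_herd_effects(data, Ainv)
  s3 <- step3_fit_rnm(data, s1$f, NULL, Ainv, fit_rm = FALSE)
  dyd <- compute_dyd(data, s3, sim$pedigree)
  ta <- 0.5 * sim$truth$true_a0[as.character(dyd$sire)]
  expect_gt(cor(dyd$dyd, ta), 0.5)
})

test_that("validation accuracy has the contracted behaviour", {
  set.seed(62)
  d <- setNames(rnorm(200), 1:200)
  expect_equal(validation_accuracy(d, d), 1)
  ## independent noise: near-zero correlation
  p <- setNames(rnorm(200), 1:200)
  expect_lt(abs(validation_accuracy(p, d)), 0.15)
  ## invariant to affine rescaling of either argument
  r0 <- validation_accuracy(p, d)
  expect_equal(validation_accuracy(2 * p + 3, d), r0)
  expect_equal(validation_accuracy(p, -1 * d), -r0)
  expect_error(validation_accuracy(setNames(rep(1, 10), 1:10),
                                   setNames(rnorm(10), 1:10)),
               "degenerate")
})

test_that("the validation split takes the youngest bulls with daughters", {
  sim <- small_sim()
  sp <- validation_split(sim$pedigree, sim$phenotypes, fraction = 0.2)
  expect_length(intersect(sp$validation, sp$training), 0)
  bd <- sim$pedigree$birthdate[match(sp$validation, sim$pedigree$id)]
  bt <- sim$pedigree$birthdate[match(sp$training, sim$pedigree$id)]
  expect_lte(max(bt), min(bd))          # validation bulls are the youngest
  expect_gte(min(bd), sp$cutoff)
  ## training data excludes validation bulls' daughters
  sire_of <- setNames(sim$pedigree$sire, sim$pedigree$id)
  expect_false(any(sire_of[as.character(sp$training_data$animal)] %in%
                     sp$validation))
})

test_that("top-k overlap shrinks as environments diverge", {
  set.seed(63)
  S <- matrix(c(1, -0.6, -0.6, 0.6), 2, 2)  # strong slope variance
  ab <- matrix(rnorm(1000), ncol = 2) %*% chol(S)
  a0 <- setNames(ab[, 1], 1:500); a1 <- setNames(ab[, 2], 1:500)
  expect_equal(top_k_overlap(a0, a1, 1.3, 1.3, k = 50), 50)
  ## zero slopes: parallel norms, full overlap at any pair
  expect_equal(top_k_overlap(a0, a1 * 0, -2, 2, k = 50), 50)
  ## widening gradient pairs never increase the overlap (nested quantiles)
  gaps <- c(0.5, 1, 2, 3, 4)
  ov <- vapply(gaps, function(g) top_k_overlap(a0, a1, -g / 2, g / 2, 50),
               integer(1))
  expect_true(all(diff(ov) <= 0))
  expect_error(top_k_overlap(a0, a1, 0, 1, k = 1000), "exceeds")
})

test_that("mean daughter gradients are record-count weighted", {
  ped <- data.frame(id = 1:5, sire = c(0, 0, 0, 1, 1),
                    dam = c(0, 0, 0, 2, 3), birthdate = 1:5,
                    sex = c("M", "F", "F", "F", "F"))
  dat <- toy_records("SIM", c(1, 1, 1), herd = c(1, 1, 2),
                     animal = c(4, 4, 5), parity = c(1, 2, 1))
  f <- c("1" = -1, "2" = 2)
  fbar <- mean_daughter_eg(c(1, 3), ped, dat, f)
  expect_equal(unname(fbar["1"]), (2 * -1 + 1 * 2) / 3)
  expect_equal(unname(fbar["3"]), 0)    # no daughters with records
})
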