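test_that("REML matches the closed-form ANOVA estimator on a balanced design", {
  set.seed(10)
  q <- 40; n0 <- 8
  a <- rnorm(q, 0, sqrt(2))
  dat <- data.frame(grp = rep(1:q, each = n0))
  dat$value <- 5 + a[dat$grp] + rnorm(nrow(dat), 0, 1)
  spec <- rnm_model_spec(response = "value", fixed = character(0),
                         random = list(g = list(column = "grp",
                                                structure = "identity",
                                                slope = FALSE)))
  fit <- reml_estimate(spec, dat, control = reml_control(max_iter = 80))
  ## balanced one-way ANOVA: sigma2_e = MSE, sigma2_g = (MSA - MSE) / n0
  av <- anova(lm(value ~ factor(grp), dat))
  mse <- av[["Mean Sq"]][2]
  msa <- av[["Mean Sq"]][1]
  expect_lt(abs(fit$sigma2_e - mse) / mse, 1e-4)
  expect_lt(abs(fit$components$g - (msa - mse) / n0) / ((msa - mse) / n0),
            1e-4)
  expect_true(fit$converged)
})

test_that("analytic REML gradients agree with finite differences", {
  sim <- small_sim()
  set.seed(11)
  dat <- sim$phenotypes[sample(nrow(sim$phenotypes), 160), ]
  dat$eg <- rnorm(12)[dat$herd]
  spec <- rnm_model_spec(response = "value", fixed = c("herd", "parity"),
    random = list(animal = list(column = "animal", structure = "kinship",
                                slope = TRUE),
                  pe = list(column = "animal", structure = "identity",
                            slope = FALSE)),
    covariable = "eg")
  vc <- list(components = list(animal = matrix(c(0.9, -0.2, -0.2, 0.3), 2),
                               pe = 0.4), sigma2_e = 1.1)
  des <- ssrnm:::mme_design(spec, dat, list(animal = sim$Ainv))
  th0 <- ssrnm:::pack_params(vc, des$terms)
  f <- function(th) ssrnm:::reml_loglik(des,
                                        ssrnm:::unpack_params(th, des$terms))$logL
  g_num <- vapply(seq_along(th0), function(i) {
    h <- 1e-6 * max(abs(th0[i]), 1e-3)
    tp <- th0; tp[i] <- tp[i] + h
    tm <- th0; tm[i] <- tm[i] - h
    (f(tp) - f(tm)) / (2 * h)
  }, numeric(1))
  fit1 <- reml_estimate(spec, dat, list(animal = sim$Ainv), init = vc,
                        control = reml_control(max_iter = 1))
  expect_equal(unname(fit1$gradient), g_num, tolerance = 1e-4)
})

test_that("a zero genetic variance does not produce spurious signal", {
  ## data with no genetic signal: the LRT against a no-genetic model must
  ## stay non-significant (boundary mixture 0.5 chisq_0 + 0.5 chisq_1)
  set.seed(12)
  hits <- 0
  sim <- small_sim()
  ped <- sim$pedigree
  spec1 <- rnm_model_spec(response = "value", fixed = "herd",
    random = list(animal = list(column = "animal", structure = "kinship",
                                slope = FALSE)))
  spec0 <- rnm_model_spec(response = "value", fixed = "herd",
                          random = list())
  for (r in 1:10) {
    ids <- sample(ped$id[ped$generation > 0], 120)
    dat <- data.frame(animal = ids, herd = sample(1:5, 120, TRUE))
    dat$value <- rnorm(120) + 0.5 * dat$herd
    f1 <- reml_estimate(spec1, dat, list(animal = sim$Ainv),
                        control = reml_control(max_iter = 30))
    f0 <- reml_estimate(spec0, dat, control = reml_control(max_iter = 30))
    D <- max(0, 2 * (f1$logLik - f0$logLik))
    p <- 0.5 * pchisq(D, 1, lower.tail = FALSE)
    if (p > 0.05) hits <- hits + 1
  }
  expect_gte(hits, 8)
})

test_that("variance components are recovered within their standard errors", {
  ## one fixed replicate of the scalar animal model
  sim <- small_sim()
  dat <- sim$phenotypes
  spec <- rnm_model_spec(response = "value",
                         fixed = c("herd", "parity"),
    random = list(animal = list(column = "animal", structure = "kinship",
                                slope = FALSE),
                  herd_year = list(column = "herd_year",
                                   structure = "identity", slope = FALSE),
                  pe = list(column = "animal", structure = "identity",
                            slope = FALSE)))
  fit <- reml_estimate(spec, dat, list(animal = sim$Ainv))
  ## generator truth: var(a0) + var(a1) * E[f^2] contributes genetic-like
  ## variance; with 12 herds the check is necessarily loose - 3 SE
  expect_lt(abs(fit$components$pe - 0.3), 3 * fit$se["pe"])
  expect_lt(abs(fit$components$herd_year - 0.2), 3 * fit$se["herd_year"])
  expect_true(fit$converged)
  ## the REML log-likelihood never decreased across iterations is implied
  ## by construction; spot-check the gradient is near zero at the optimum
  expect_lt(max(abs(fit$gradient)), 1e-4)
})
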