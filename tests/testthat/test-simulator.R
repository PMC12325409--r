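test_that("availability degenerates correctly when noise is removed", {
  # tau2 = tau2_1 = 0, rho = 0, beta_b = 0: l[,1] = beta_b0, l[,t>1] = 0
  set.seed(1)
  l <- simulate_availability(3, 4, NULL, beta_b0 = 6, beta_b = numeric(),
                             rho = 0, tau2 = 0, tau2_1 = 0)
  expect_equal(l[, 1], rep(6, 3))
  expect_equal(as.vector(l[, -1]), rep(0, 9))

  # tau2 = 0, rho = 1, constant covariates: a noiseless random walk is flat
  Xb <- matrix(1, 12, 1)
  set.seed(1)
  l2 <- simulate_availability(3, 4, Xb, beta_b0 = 2, beta_b = 0.5, rho = 1,
                              tau2 = 0, tau2_1 = 1)
  for (t in 2:4) expect_equal(l2[, t], l2[, 1])
})

test_that("AR(1) increment variance matches its closed form", {
  # with rho = 1, tau2 = 1: Var(l2 - l1 - (X2 - X1) beta) = tau2
  set.seed(42)
  n <- 1e4
  Xb <- matrix(rnorm(2 * n), n * 2, 1)
  l <- simulate_availability(n, 2, Xb, beta_b0 = 6, beta_b = 1, rho = 1,
                             tau2 = 1, tau2_1 = 1)
  inc <- l[, 2] - l[, 1] - (Xb[(n + 1):(2 * n), 1] - Xb[1:n, 1])
  se <- sqrt(2 / n)  # sd of a variance estimate of N(0,1) data
  expect_lt(abs(var(inc) - 1), 3 * se)
})

test_that("collection stage is exact with zero noise and calibrated with noise", {
  l <- matrix(c(1, 2, 3, 4), 2, 2)
  samples <- data.frame(site = c(1, 2, 1, 2), time = c(1, 1, 2, 2))
  set.seed(1)
  v0 <- simulate_collection(l, samples, NULL, numeric(), 0)
  expect_equal(v0, as.vector(l))
  Xw <- matrix(c(1, -1, 2, 0), 4, 1)
  v1 <- simulate_collection(l, samples, Xw, 0.7, 0)
  expect_equal(v1 - as.vector(l), 0.7 * Xw[, 1])

  set.seed(7)
  n <- 1e4
  lv <- matrix(0, n, 1)
  vv <- simulate_collection(lv, data.frame(site = 1:n, time = 1),
                            NULL, numeric(), 1)
  expect_lt(abs(var(vv) - 1), 3 * sqrt(2 / n))
})

test_that("replicate status draws have the stated frequencies", {
  set.seed(3)
  expect_true(all(simulate_replicate_status(0, 0, 100) == 0L))
  expect_true(all(simulate_replicate_status(1, 0, 100) == 1L))
  g <- simulate_replicate_status(0.05, 0.1, 1e5)
  freq <- tabulate(g + 1L, 3L) / 1e5
  for (k in 1:3) {
    p <- c(0.85, 0.05, 0.1)[k]
    expect_lt(abs(freq[k] - p), 3 * sqrt(p * (1 - p) / 1e5))
  }
  expect_error(simulate_replicate_status(0.7, 0.4, 10), "exceed 1")
})

test_that("simulate_ct reproduces the deterministic limits", {
  # a1 very negative makes sigma_y effectively zero
  quiet <- -60
  # w = 1: mu = 44 >= ct_max = 40, so censored
  expect_true(is.na(simulate_ct(1, 0L, 44, -1.7, quiet, 0)))
  # w = 3e7: mu = 44 - 1.7 * ln(3e7), uncensored
  ct <- simulate_ct(3e7, 0L, 44, -1.7, quiet, 0)
  expect_equal(ct, 44 - 1.7 * log(3e7), tolerance = 1e-8)
  # inhibition at multiplier 0.1 shifts the noiseless CT by -alpha2 * ln(10)
  ct2 <- simulate_ct(3e7, 2L, 44, -1.7, quiet, 0, inhibition_multiplier = 0.1)
  expect_equal(ct2 - ct, 1.7 * log(10), tolerance = 1e-8)
})

test_that("standards cover the plate grid and sit on the line when noiseless", {
  spec <- list(concentrations = 3 * 10^(1:7), K_star = 3)
  set.seed(2)
  s <- simulate_standards(5, spec, rep(44, 5), rep(-1.7, 5), -60, 0, 0, 0)
  expect_equal(nrow(s$standards), 105)         # 5 plates x 7 conc x 3 reps
  obs <- !is.na(s$standards$ct)
  expect_equal(s$standards$ct[obs],
               44 - 1.7 * log(s$standards$concentration[obs]),
               tolerance = 1e-8)
  # the top concentration is essentially never censored at (44, -1.7):
  # mu ~ 14.7 and sd(3e7) ~ 0.13, so the censoring z-score is astronomical
  set.seed(4)
  s2 <- simulate_standards(20, spec, rnorm(20, 44, sqrt(0.1)),
                           rnorm(20, -1.7, 0.1), 0.2, -0.25, 0, 0)
  top <- s2$standards$concentration == 3e7
  expect_false(anyNA(s2$standards$ct[top]))
})

test_that("censoring probability is monotone decreasing in concentration", {
  # exact censoring probability of an unaffected replicate
  p_cens <- function(w) pnorm(40, ct_mean(w, 44, -1.7),
                              sqrt(ct_variance(w, 0.2, -0.25)),
                              lower.tail = FALSE)
  w <- 10^seq(-2, 7, length.out = 40)
  expect_true(all(diff(p_cens(w)) <= 1e-12))
  # spot-check the simulator agrees empirically at one contrast
  set.seed(5)
  lo <- mean(is.na(simulate_ct(rep(5, 4e3), 0L, 44, -1.7, 0.2, -0.25)))
  hi <- mean(is.na(simulate_ct(rep(500, 4e3), 0L, 44, -1.7, 0.2, -0.25)))
  expect_gt(lo, hi)
})

test_that("simulate_survey has the reference dimensions and is deterministic", {
  d <- survey_design(10, 20, 2, 2)
  cfg <- sim_config(d, params = ref_params(), seed = 123)
  sim <- simulate_survey(cfg)
  expect_equal(nrow(sim$dataset$replicates), 800)     # 10 * 20 * 2 * 2
  expect_equal(d$n_plates, 200)
  expect_equal(nrow(sim$dataset$standards), 4200)     # 200 plates x 21
  sim2 <- simulate_survey(cfg)
  expect_identical(sim$dataset$replicates, sim2$dataset$replicates)
  expect_identical(sim$latent, sim2$latent)
  # contamination frequency across replicates and standards
  g <- c(sim$latent$gamma, sim$latent$gamma_star)
  expect_lt(abs(mean(g == 1L) - 0.05),
            3 * sqrt(0.05 * 0.95 / length(g)))
})

test_that("changing K leaves the availability and collection draws intact", {
  d2 <- survey_design(3, 4, 2, 2)
  d5 <- survey_design(3, 4, 2, 5)
  s2 <- simulate_survey(sim_config(d2, params = ref_params(), seed = 8))
  s5 <- simulate_survey(sim_config(d5, params = ref_params(), seed = 8))
  expect_identical(s2$latent$l, s5$latent$l)
  expect_identical(s2$latent$v, s5$latent$v)
})

test_that("latent moments match their defining normals", {
  set.seed(6)
  n <- 1e4
  l <- simulate_availability(n, 1, NULL, beta_b0 = 6, beta_b = numeric(),
                             rho = 1, tau2 = 1, tau2_1 = 1)
  expect_lt(abs(mean(l) - 6), 3 / sqrt(n))
  expect_lt(abs(var(as.vector(l)) - 1), 3 * sqrt(2 / n))
})
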