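test_that("ct_mean and ct_variance evaluate the stated regressions", {
  expect_equal(ct_mean(1, 44, -1.7), 44)               # ln 1 = 0
  expect_equal(ct_mean(3e7, 44, -1.7), 44 - 1.7 * log(3e7))  # ~ 14.7316
  w <- c(0.5, 3, 2e4)
  expect_equal(ct_mean(10 * w, 44, -1.7) - ct_mean(w, 44, -1.7),
               rep(-1.7 * log(10), 3))
  expect_error(ct_mean(0, 44, -1.7), "positive")

  expect_equal(ct_variance(1, 0.2, -0.25), exp(0.2))   # ~ 1.2214
  expect_equal(ct_variance(c(1, 7, 100), 0.2, 0), rep(exp(0.2), 3))
  expect_equal(ct_variance(3e7, 0.2, -0.25), exp(0.2 - 0.25 * log(3e7)))
  # with a2 < 0 the variance strictly decreases in w
  wseq <- 10^seq(-3, 7, length.out = 50)
  expect_true(all(diff(ct_variance(wseq, 0.2, -0.25)) < 0))
})

test_that("component log-densities match independent truncated-normal oracles", {
  # censored unaffected replicate with mu at the censoring limit: half mass
  expect_equal(replicate_component_loglik(NA, w = exp((44 - 40) / 1.7),
                                          gamma = 0, 44, -1.7,
                                          a1 = 0.2, a2 = -0.25,
                                          sigma_c = 40, ct_max = 40),
               log(0.5), tolerance = 1e-9)
  # censored inhibited replicate with mu = ct_max: entire support is beyond
  expect_equal(replicate_component_loglik(NA, w = exp((44 - 40) / 1.7),
                                          gamma = 2, 44, -1.7, 0.2, -0.25,
                                          sigma_c = 40, ct_max = 40), 0)
  # observed contaminated replicate vs a quadrature-normalised density
  mu <- ct_mean(50, 44, -1.7); sc <- 40
  ct <- 15
  dens <- function(x) dnorm(x, mu, sc)
  Z <- integrate(dens, 0, mu, rel.tol = 1e-12)$value
  oracle <- log(dens(ct) / Z)
  expect_equal(replicate_component_loglik(ct, 50, 1, 44, -1.7, 0.2, -0.25,
                                          sc, 40), oracle,
               tolerance = 1e-10)
  # same via the closed form phi((ct-mu)/sc)/sc / (Phi(0) - Phi(-mu/sc))
  oracle2 <- log(dnorm((ct - mu) / sc) / sc /
                   (pnorm(0) - pnorm(-mu / sc)))
  expect_equal(replicate_component_loglik(ct, 50, 1, 44, -1.7, 0.2, -0.25,
                                          sc, 40), oracle2,
               tolerance = 1e-10)
  # gamma = 1 with mu <= 0 has empty support
  expect_identical(replicate_component_loglik(10, w = exp(30), gamma = 1,
                                              44, -1.7, 0.2, -0.25, 40, 40),
                   -Inf)
})

test_that("compiled and reference component kernels agree exactly", {
  set.seed(20)
  nn <- 500
  ct <- runif(nn, 1, 39.9); ct[sample(nn, 120)] <- NA
  mu <- runif(nn, -10, 60); sdy <- runif(nn, 0.05, 4)
  for (g in 0:2) {
    a <- ednaconc:::.comp_ll_r(ct, mu, sdy, rep(g, nn), 40, 40)
    b <- ednaconc:::.comp_ll_cpp(ct, mu, sdy, rep(as.integer(g), nn), 40, 40)
    expect_identical(is.finite(a), is.finite(b))
    expect_equal(a[is.finite(a)], b[is.finite(b)], tolerance = 1e-12)
  }
})

test_that("the mixture marginal is a proper law and has the stated limits", {
  # p_c = p_h = 0 equals the unaffected component exactly
  ct <- c(12, 25, NA, 38)
  w <- c(1e5, 30, 0.5, 2)
  L0 <- replicate_component_loglik(ct, w, 0, 44, -1.7, 0.2, -0.25, 40, 40)
  expect_equal(replicate_marginal_loglik(ct, w, 0, 0, 44, -1.7, 0.2, -0.25,
                                         40, 40), L0)
  # quadrature + censoring mass integrates to one
  for (w0 in c(0.5, 50, 1e4)) {
    f <- function(x) exp(replicate_marginal_loglik(x, w0, 0.05, 0.1, 44,
                                                   -1.7, 0.2, -0.25, 40, 40))
    area <- integrate(Vectorize(f), -Inf, 40, rel.tol = 1e-9)$value
    mass <- exp(replicate_marginal_loglik(NA, w0, 0.05, 0.1, 44, -1.7,
                                          0.2, -0.25, 40, 40))
    expect_equal(area + mass, 1, tolerance = 1e-6)
  }
  # the marginal dominates each weighted component (all terms non-negative)
  lm_ <- replicate_marginal_loglik(5, 30, 0.05, 0.1, 44, -1.7, 0.2, -0.25,
                                   40, 40)
  l1 <- replicate_component_loglik(5, 30, 1, 44, -1.7, 0.2, -0.25, 40, 40)
  expect_gte(lm_, log(0.05) + l1)
  expect_error(replicate_marginal_loglik(5, 30, 0.3, 0.3, 44, -1.7,
                                         0.2, -0.25, 40, 40), "0.5")
})

test_that("stage log-densities match flat-loop oracles", {
  # availability at its conditional means: all z-scores zero
  n <- 3; T <- 4
  Xb <- matrix(rnorm(n * T), n * T, 1)
  eta <- matrix(Xb, n, T)
  l <- matrix(0, n, T)
  l[, 1] <- 2 + eta[, 1]
  for (t in 2:T) l[, t] <- 0.8 * (l[, t - 1] - eta[, t - 1]) + eta[, t]
  expect_equal(availability_loglik(l, Xb, 2, 1, 0.8, 1, 1),
               -(n * T / 2) * log(2 * pi))
  # T = 1 reduces to the first-occasion term
  expect_equal(availability_loglik(l[, 1, drop = FALSE],
                                   Xb[1:n, , drop = FALSE], 2, 1, 0.8, 1, 1),
               -(n / 2) * log(2 * pi))
  # random instance vs an independent term-by-term oracle
  set.seed(9)
  l2 <- matrix(rnorm(6, 3), 2, 3)
  Xb2 <- matrix(rnorm(6), 6, 1)
  eta2 <- matrix(Xb2 * 0.5, 2, 3)
  rho <- c(0.7, 1.1)
  oracle <- oracle_dnorm_sum(l2[, 1], 1.5 + eta2[, 1], sqrt(0.8))
  for (t in 2:3) for (i in 1:2)
    oracle <- oracle + oracle_dnorm_sum(l2[i, t],
                                        rho[i] * (l2[i, t - 1] - eta2[i, t - 1]) +
                                          eta2[i, t], sqrt(0.3))
  expect_equal(availability_loglik(l2, Xb2, 1.5, 0.5, rho, 0.3, 0.8),
               oracle, tolerance = 1e-12)
})

test_that("collection and hierarchy log-densities match oracles", {
  l <- matrix(c(1, 2, 3, 4), 2, 2)
  samples <- data.frame(site = c(1, 1, 2), time = c(1, 2, 2))
  v <- as.vector(l)[c(1, 3, 4)]
  expect_equal(collection_loglik(v, l, samples, NULL, numeric(), 1),
               -(3 / 2) * log(2 * pi))
  # beta_w = 0 makes the density independent of the covariates
  Xw <- matrix(rnorm(3), 3, 1)
  expect_equal(collection_loglik(v, l, samples, Xw, 0, 2),
               collection_loglik(v, l, samples, NULL, numeric(), 2))
  set.seed(4)
  v2 <- rnorm(3); bw <- 0.4
  oracle <- oracle_dnorm_sum(v2, as.vector(l)[c(1, 3, 4)] + bw * Xw[, 1],
                             sqrt(1.7))
  expect_equal(collection_loglik(v2, l, samples, Xw, bw, 1.7), oracle,
               tolerance = 1e-12)

  set.seed(5)
  rho <- rnorm(3, 1, 0.1); a1p <- rnorm(2, 44); a2p <- rnorm(2, -1.7)
  oracle2 <- oracle_dnorm_sum(rho, 1, sqrt(0.05)) +
    oracle_dnorm_sum(a1p, 44, sqrt(0.1)) +
    oracle_dnorm_sum(a2p, -1.7, sqrt(0.1))
  expect_equal(hierarchy_loglik(rho, 1, 0.05, a1p, a2p, 44, -1.7, 0.1),
               oracle2, tolerance = 1e-12)
  # degenerate case: all values at their hierarchical means
  expect_equal(hierarchy_loglik(rep(1, 4), 1, 2, rep(44, 3), rep(-1.7, 3),
                                44, -1.7, 2),
               -(4 + 6) / 2 * log(2 * pi * 2))
})

test_that("joint log-posterior respects the probability constraint and sums
          the named densities on a tiny instance", {
  sim <- tiny_sim(seed = 3, M = 1, K = 1, n = 1, T = 1)
  bad <- sim$params
  bad$p_c <- 0.3; bad$p_h <- 0.3
  expect_identical(joint_log_posterior(bad, sim$latent, sim$dataset), -Inf)

  # independent oracle: every density summed by hand on (n,T,M,K) = 1
  p <- sim$params
  lat <- sim$latent
  pk <- ednaconc:::.pack(sim$dataset)
  pr <- default_priors()
  oracle <- oracle_dnorm_sum(lat$l[1, 1],
                             p$beta_b0 + drop(pk$Xb %*% p$beta_b),
                             sqrt(p$tau2_1)) +
    oracle_dnorm_sum(lat$v, lat$l[1, 1] + drop(pk$Xw %*% p$beta_w),
                     sqrt(p$sigma2)) +
    oracle_dnorm_sum(p$rho, p$rho0, sqrt(p$sigma2_rho)) +
    oracle_dnorm_sum(p$alpha1, p$alpha1_0, sqrt(p$sigma2_alpha)) +
    oracle_dnorm_sum(p$alpha2, p$alpha2_0, sqrt(p$sigma2_alpha))
  ct_all <- c(pk$ct, pk$s_ct)
  w_all <- exp(c(lat$v[pk$rs], pk$s_logw))
  g_all <- c(lat$gamma, lat$gamma_star)
  plates <- c(pk$rp, pk$sp)
  for (r in seq_along(ct_all)) {
    oracle <- oracle + replicate_component_loglik(
      ct_all[r], w_all[r], g_all[r], p$alpha1[plates[r]],
      p$alpha2[plates[r]], p$a1, p$a2, p$sigma_c, pk$ct_max)
    oracle <- oracle + c(log1p(-p$p_c - p$p_h), log(p$p_c),
                         log(p$p_h))[g_all[r] + 1L]
  }
  oracle <- oracle + ednaconc:::.prior_ll(p, pr, "full")
  expect_equal(joint_log_posterior(p, lat, sim$dataset, pr), oracle,
               tolerance = 1e-10)
  # dropping the standards strictly reduces the summed terms
  no_std <- sim$dataset
  no_std$standards <- no_std$standards[0, ]
  lat2 <- lat; lat2$gamma_star <- integer(0)
  expect_gt(joint_log_posterior(p, lat2, no_std, pr),
            joint_log_posterior(p, lat, sim$dataset, pr))
})

test_that("model variants collapse to the full model in their limits", {
  sim <- tiny_sim(seed = 6)
  p <- sim$params
  # NO_MIXTURE equals FULL with p_c = p_h = 0 exactly
  p0 <- p; p0$p_c <- 0; p0$p_h <- 0
  lat0 <- sim$latent
  lat0$gamma <- rep(0L, length(lat0$gamma))
  lat0$gamma_star <- rep(0L, length(lat0$gamma_star))
  expect_equal(joint_log_posterior(p0, lat0, sim$dataset, variant = "full"),
               joint_log_posterior(p0, lat0, sim$dataset,
                                   variant = "no_mixture"))
  # CONST_VAR with sigma2_P = sigma2_y(w0) equals FULL at that single
  # concentration
  w0 <- 500
  s2 <- ct_variance(w0, p$a1, p$a2)
  ct <- c(28, NA, 31)
  full <- replicate_component_loglik(ct, w0, 0, 44, -1.7, p$a1, p$a2, 40, 40)
  cv <- replicate_component_loglik(ct, w0, 0, 44, -1.7, 0, 0, 40, 40,
                                   variant = "const_var", sigma2_P = s2)
  expect_equal(full, cv, tolerance = 1e-12)
})
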