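test_that("initialization inverts noiseless standards exactly", {
  # noiseless standards fall on each plate's line, so per-plate OLS recovers
  # the coefficients and sample v comes from inverting the line
  d <- survey_design(2, 2, 2, 2)
  p0 <- ref_params(p_c = 0, p_h = 0, a1 = -60, beta_b0 = 8)
  sim <- simulate_survey(sim_config(
    d, params = p0,
    plate_coef_spec = list(mean1 = 44, var1 = 1e-20, mean2 = -1.7,
                           var2 = 1e-20), seed = 4))
  st <- initialize_state(sim$dataset, "full", 1)
  expect_equal(st$params$alpha1, sim$params$alpha1, tolerance = 1e-6)
  expect_equal(st$params$alpha2, sim$params$alpha2, tolerance = 1e-6)
  # with zero CT noise the inverted v equals the true v for uncensored cells
  pk <- ednaconc:::.pack(sim$dataset)
  all_obs <- tapply(!is.na(pk$ct), pk$rs, all)
  idx <- which(as.logical(all_obs))
  expect_equal(st$latent$v[idx], sim$latent$v[idx], tolerance = 1e-6)
  expect_true(all(st$latent$gamma == 0L))
  expect_equal(st$params$p_c, 0.01)
  # deterministic given the seed
  st2 <- initialize_state(sim$dataset, "full", 1)
  expect_identical(st, st2)
})

test_that("all-censored samples initialise at the censoring boundary", {
  sim <- tiny_sim(seed = 2, beta_b0 = -20)   # essentially nothing amplifies
  expect_true(anyNA(sim$dataset$replicates$ct))
  st <- initialize_state(sim$dataset, "full", 1)
  pk <- ednaconc:::.pack(sim$dataset)
  cens_samples <- which(as.logical(tapply(is.na(pk$ct), pk$rs, all)))
  plate_of <- pk$samples$plate[cens_samples]
  expect_equal(st$latent$v[cens_samples],
               (40 - st$params$alpha1[plate_of]) / st$params$alpha2[plate_of])
})

test_that("the status full conditional matches brute-force enumeration", {
  # one replicate, all parameters fixed: enumerate the three joint densities
  ct <- 33; w <- 40
  pr <- gamma_fullcond_probs(ct, w, p_c = 0.05, p_h = 0.1, 44, -1.7,
                             0.2, -0.25, sigma_c = 40, ct_max = 40)
  mu <- 44 - 1.7 * log(w)
  sdy <- sqrt(exp(0.2 - 0.25 * log(w)))
  brute <- c(0.85 * dnorm(ct, mu, sdy),
             0.05 * dnorm(ct, mu, 40) / (pnorm(mu, mu, 40) - pnorm(0, mu, 40)),
             0.10 * dnorm(ct, mu, 40) / 0.5 * (ct > mu))
  brute <- brute / sum(brute)
  expect_lt(sum(abs(pr[1, ] - brute)) / 2, 1e-10)   # total variation
  # p_c = p_h = 0 keeps every indicator at zero
  set.seed(1)
  g <- update_gamma(c(30, NA, 20), c(10, 1, 1000), 0, 0, 44, -1.7, 0.2,
                    -0.25, 40, 40)
  expect_true(all(g == 0L))
  # a replicate sitting exactly at mu with tiny CT sd is surely unaffected
  pr2 <- gamma_fullcond_probs(mu, w, 0.05, 0.1, 44, -1.7, -30, 0, 40, 40)
  expect_gt(pr2[1, 1], 1 - 1e-6)
})

test_that("probability proposals obey the joint rejection constraint", {
  set.seed(2)
  counts <- c(900, 50, 50)
  # a proposal across the boundary is rejected outright
  r <- propose_probabilities(0.3, 0.19, counts, step = 1e-9)
  expect_false(r$constraint_rejected)   # 0.49 + tiny step stays inside
  blocked <- 0
  p <- c(0.05, 0.1)
  for (i in 1:10000) {
    r <- propose_probabilities(p[1], p[2], counts, step = 0.05)
    p <- c(r$p_c, r$p_h)
    expect_lt(sum(p), 0.5)
    expect_true(all(p >= 0))
    blocked <- blocked + r$constraint_rejected
  }
  expect_gt(blocked, 0)   # the constraint actually bites at step 0.05
  expect_error(propose_probabilities(0.3, 0.25, counts), "0.5")
})

test_that("fits are deterministic given the seed", {
  sim <- tiny_sim(seed = 7)
  ctl <- mcmc_control(n_iter = 120, n_burnin = 60, thin = 2, n_chains = 1,
                      seed = 9)
  f1 <- fit_edna(sim$dataset, control = ctl)
  f2 <- fit_edna(sim$dataset, control = ctl)
  expect_identical(f1$params, f2$params)
  expect_identical(f1$l, f2$l)
  expect_identical(f1$gamma_prob, f2$gamma_prob)
})

test_that("every retained draw satisfies the parameter constraints", {
  sim <- tiny_sim(seed = 13)
  fit <- fit_edna(sim$dataset, control = mcmc_control(
    n_iter = 400, n_burnin = 100, thin = 1, n_chains = 1, seed = 2))
  dr <- fit$params
  expect_true(all(dr[, "p_c"] >= 0))
  expect_true(all(dr[, "p_h"] >= 0))
  expect_true(all(dr[, "p_c"] + dr[, "p_h"] < 0.5))
  for (vp in c("tau2", "tau2_1", "sigma2", "sigma2_rho", "sigma2_alpha"))
    expect_true(all(dr[, vp] > 0))
})

test_that("the sampler's stationary status marginal matches enumeration on a
          tiny instance", {
  # n = T = M = 1, K = 2, 3 standards; all parameters and l fixed at truth,
  # only v and gamma updated. The exact marginal P(gamma_k = g | data) is
  # obtained by enumerating the 9 gamma pairs and integrating v numerically.
  d <- survey_design(1, 1, 1, 2, ct_max = 40)
  p0 <- ref_params(p_c = 0.15, p_h = 0.2, beta_b0 = 3)
  cfg <- sim_config(d, params = p0,
                    covariate_spec = list(n_site_continuous = 0,
                                          n_site_binary = 0,
                                          n_sample_continuous = 0,
                                          n_sample_binary = 0),
                    standards_spec = list(concentrations = c(30, 3e3, 3e5),
                                          K_star = 1), seed = 5)
  sim <- simulate_survey(cfg)
  expect_equal(nrow(sim$dataset$replicates), 2)

  truth <- sim$params
  l0 <- sim$latent$l[1, 1]
  pk <- ednaconc:::.pack(sim$dataset)
  # exact enumeration over the environmental gamma pair, v integrated out
  wts <- c(1 - truth$p_c - truth$p_h, truth$p_c, truth$p_h)
  joint <- matrix(NA_real_, 3, 3)
  for (g1 in 0:2) for (g2 in 0:2) {
    f <- function(v) {
      out <- numeric(length(v))
      for (ii in seq_along(v)) {
        out[ii] <- exp(
          dnorm(v[ii], l0, sqrt(truth$sigma2), log = TRUE) +
            replicate_component_loglik(pk$ct[1], exp(v[ii]), g1,
                                       truth$alpha1[1], truth$alpha2[1],
                                       truth$a1, truth$a2, truth$sigma_c,
                                       40) +
            replicate_component_loglik(pk$ct[2], exp(v[ii]), g2,
                                       truth$alpha1[1], truth$alpha2[1],
                                       truth$a1, truth$a2, truth$sigma_c,
                                       40))
      }
      out
    }
    joint[g1 + 1, g2 + 1] <- wts[g1 + 1] * wts[g2 + 1] *
      integrate(f, l0 - 12, l0 + 12, rel.tol = 1e-10)$value
  }
  joint <- joint / sum(joint)
  exact1 <- rowSums(joint); exact2 <- colSums(joint)

  init <- initialize_state(sim$dataset, "full", 1)
  init$params <- truth
  init$latent$l <- sim$latent$l
  init$latent$v <- sim$latent$v
  fit <- fit_edna(sim$dataset, control = mcmc_control(
    n_iter = 6000, n_burnin = 500, thin = 1, n_chains = 1, seed = 11,
    blocks = c("v", "gamma"), save_gamma = TRUE, jitter_init = 0),
    init = init)
  emp1 <- tabulate(fit$gamma[, 1] + 1L, 3L) / nrow(fit$gamma)
  emp2 <- tabulate(fit$gamma[, 2] + 1L, 3L) / nrow(fit$gamma)
  # 3 Monte-Carlo standard errors on the least-frequent class, inflated for
  # autocorrelation (the chain updates v and gamma jointly)
  n_eff <- nrow(fit$gamma) / 5
  for (g in 1:3) {
    se1 <- sqrt(exact1[g] * (1 - exact1[g]) / n_eff)
    se2 <- sqrt(exact2[g] * (1 - exact2[g]) / n_eff)
    expect_lt(abs(emp1[g] - exact1[g]), 3 * se1 + 1e-3)
    expect_lt(abs(emp2[g] - exact2[g]), 3 * se2 + 1e-3)
  }
})

test_that("NO_MIXTURE and FULL agree on clean data", {
  d <- survey_design(2, 3, 2, 2)
  sim <- simulate_survey(sim_config(d, params = ref_params(p_c = 0,
                                                           p_h = 0),
                                    seed = 3))
  ctl <- mcmc_control(n_iter = 500, n_burnin = 250, thin = 1, n_chains = 1,
                      seed = 4)
  f_full <- fit_edna(sim$dataset, variant = "full", control = ctl)
  f_nm <- fit_edna(sim$dataset, variant = "no_mixture", control = ctl)
  # posterior means of l agree within Monte-Carlo error
  dd <- colMeans(f_full$l) - colMeans(f_nm$l)
  pooled_sd <- sqrt(apply(f_full$l, 2, var) / nrow(f_full$l) * 5 +
                      apply(f_nm$l, 2, var) / nrow(f_nm$l) * 5)
  expect_lt(mean(abs(dd) / (pooled_sd + 0.05)), 3)
})

test_that("posterior predictive CT summaries behave", {
  sim <- tiny_sim(seed = 4)
  fit <- fit_edna(sim$dataset, control = mcmc_control(
    n_iter = 200, n_burnin = 100, thin = 1, n_chains = 1, seed = 6))
  # degenerate draws: a single parameter set gives closed-form summaries
  one <- fit
  one$params <- fit$params[1, , drop = FALSE]
  pp <- posterior_predict_ct(one, w_grid = 1000, plate = 1)
  al1 <- one$params[1, "alpha1[1]"]; al2 <- one$params[1, "alpha2[1]"]
  mu <- al1 + al2 * log(1000)
  sdy <- exp((one$params[1, "a1"] + one$params[1, "a2"] * log(1000)) / 2)
  pc <- one$params[1, "p_c"]; ph <- one$params[1, "p_h"]
  expect_lt(abs(pp$p_censored -
                  ((1 - pc - ph) * pnorm(40, mu, sdy, lower.tail = FALSE) +
                     pc * (pnorm(mu, mu, 40) - pnorm(40, mu, 40)) /
                     (pnorm(mu, mu, 40) - pnorm(0, mu, 40)) * (mu > 40) +
                     ph * (1 - pmin(pnorm(40, mu, 40) - 0.5, 0.5) / 0.5))),
            0.02)
  # interval width of the unaffected law grows as concentration shrinks
  # (a2 < 0); use a degenerate mixture-free draw away from the censoring
  # boundary so the comparison isolates the heteroscedastic variance
  two <- fit
  two$params <- fit$params[1, , drop = FALSE]
  two$params[1, c("p_c", "p_h")] <- 0
  two$params[1, c("alpha1[1]", "alpha2[1]")] <- c(44, -1.7)
  two$params[1, c("a1", "a2")] <- c(0.2, -0.25)
  pp2 <- posterior_predict_ct(two, w_grid = c(1e3, 1e6), plate = 1)
  expect_gt(pp2$upper[1] - pp2$lower[1], pp2$upper[2] - pp2$lower[2])
  expect_lt(pp2$p_censored[2], 1e-6)   # far above the largest standard
  expect_error(posterior_predict_ct(fit, numeric(0)), "non-empty")
})
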