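#' Configuration for synthetic qPCR surveys
#'
#' Bundles the survey design, the true model parameters, the covariate
#' distributions, the contamination/inhibition mechanisms and the standards
#' layout. Defaults reproduce the reference simulation setting: one standard
#' normal and one Bernoulli(0.5) covariate at both the site and the sample
#' level; contaminant DNA amount `lambda ~ N(3e3, sd = 100)` truncated to be
#' positive; inhibition delaying amplification as if the concentration were
#' 90% lower (multiplier 0.1); plate standard-curve coefficients drawn from
#' N(44, 0.1) and N(-1.7, 0.01) (second argument a variance); standards of
#' `K_star = 3` replicates at seven concentrations `3 x 10^z`, `z = 1..7`.
#'
#' @param design an [survey_design()] object.
#' @param params true [model_parameters()]; `rho` is recycled to the number
#'   of sites; `alpha1`/`alpha2` are ignored (plate coefficients are drawn
#'   from `plate_coef_spec`).
#' @param covariate_spec list with `n_site_continuous`, `n_site_binary`,
#'   `n_sample_continuous`, `n_sample_binary` counts.
#' @param contamination_spec list with `mean` and `sd` of the added DNA
#'   amount.
#' @param inhibition_multiplier effective-concentration multiplier in (0,1).
#' @param standards_spec list with `concentrations` and `K_star`.
#' @param plate_coef_spec list with `mean1`, `var1`, `mean2`, `var2` for the
#'   per-plate intercept and slope draws.
#' @param seed integer seed controlling the whole survey (sub-streams per
#'   generation stage, so e.g. changing K leaves availability draws intact).
#' @return A list of class `edna_sim_config`.
#' @export
sim_config <- function(design,
                       params = model_parameters(
                         beta_b0 = 6, beta_b = c(1, -1), beta_w = c(1, -1),
                         rho = 1, rho0 = 1, tau2 = 1, tau2_1 = 1, sigma2 = 1,
                         a1 = 0.2, a2 = -0.25, p_c = 0.05, p_h = 0.1,
                         sigma_c = 40, ct_max = 40),
                       covariate_spec = list(n_site_continuous = 1,
                                             n_site_binary = 1,
                                             n_sample_continuous = 1,
                                             n_sample_binary = 1),
                       contamination_spec = list(mean = 3e3, sd = 100),
                       inhibition_multiplier = 0.1,
                       standards_spec = list(concentrations = 3 * 10^(1:7),
                                             K_star = 3),
                       plate_coef_spec = list(mean1 = 44, var1 = 0.1,
                                              mean2 = -1.7, var2 = 0.01),
                       seed = 1L) {
  stopifnot(inherits(design, "edna_design"),
            contamination_spec$mean > 0, contamination_spec$sd > 0,
            inhibition_multiplier > 0, inhibition_multiplier < 1,
            all(standards_spec$concentrations > 0),
            .is_count(standards_spec$K_star))
  structure(list(design = design, params = params,
                 covariate_spec = covariate_spec,
                 contamination_spec = contamination_spec,
                 inhibition_multiplier = inhibition_multiplier,
                 standards_spec = standards_spec,
                 plate_coef_spec = plate_coef_spec,
                 seed = as.integer(seed)),
            class = "edna_sim_config")
}

#' Simulate the latent availability process
#'
#' Draws the `n x T` log-DNA availability matrix:
#' `l[i,1] ~ N(beta_b0 + X^b[i,1] beta_b, tau2_1)` then
#' `l[i,t] ~ N(rho[i] (l[i,t-1] - X^b[i,t-1] beta_b) + X^b[i,t] beta_b, tau2)`.
#'
#' @param X_b site covariates (`NULL`, `(n*T) x q` matrix in occasion order,
#'   or `n x T x q` array).
#' @param beta_b0,beta_b,rho,tau2,tau2_1 availability parameters.
#' @param n,T numbers of sites and occasions.
#' @return `n x T` matrix.
#' @export
simulate_availability <- function(n, T, X_b, beta_b0, beta_b, rho,
                                  tau2, tau2_1) {
  if (T < 1) stop("T must be at least 1")
  xb <- .coerce_xb(X_b, n, T)
  eta <- .eta_matrix(xb, beta_b, n, T)
  rho <- rep_len(rho, n)
  l <- matrix(NA_real_, n, T)
  l[, 1L] <- stats::rnorm(n, beta_b0 + eta[, 1L], sqrt(tau2_1))
  if (T > 1L) for (t in 2:T)
    l[, t] <- stats::rnorm(n, rho * (l[, t - 1L] - eta[, t - 1L]) + eta[, t],
                           sqrt(tau2))
  l
}

#' Simulate sample log-DNA at the collection stage
#'
#' `v[s] ~ N(l[i(s), t(s)] + X^w[s] beta_w, sigma2)`, independent across
#' samples.
#'
#' @param l `n x T` availability matrix.
#' @param samples data.frame with `site`, `time` per sample.
#' @param X_w sample covariate matrix (or `NULL`).
#' @param beta_w,sigma2 collection parameters.
#' @return Numeric vector aligned with `samples`.
#' @export
simulate_collection <- function(l, samples, X_w, beta_w, sigma2) {
  if (sigma2 < 0) stop("sigma2 must be non-negative")
  if (any(!is.finite(l))) stop("l must be finite")
  occ <- (samples$time - 1L) * nrow(l) + samples$site
  m <- as.vector(l)[occ]
  if (!is.null(X_w) && ncol(as.matrix(X_w)) > 0L && length(beta_w))
    m <- m + drop(as.matrix(X_w) %*% beta_w)
  stats::rnorm(length(m), m, sqrt(sigma2))
}

#' Simulate replicate contamination/inhibition indicators
#'
#' i.i.d. categorical draws: contaminated (1) with probability `p_c`,
#' inhibited (2) with probability `p_h`, unaffected (0) otherwise.
#'
#' @param p_c,p_h probabilities, `p_c + p_h <= 1`.
#' @param n_draws number of indicators to draw.
#' @return Integer vector in `{0, 1, 2}`.
#' @export
simulate_replicate_status <- function(p_c, p_h, n_draws) {
  if (p_c < 0 || p_h < 0) stop("probabilities must be non-negative")
  if (p_c + p_h > 1) stop("p_c + p_h must not exceed 1")
  u <- stats::runif(n_draws)
  ifelse(u < p_c, 1L, ifelse(u < p_c + p_h, 2L, 0L))
}

#' Simulate CT values for replicates of known DNA amount
#'
#' Generates uncensored CT values and censors them at `ct_max`. Unaffected
#' replicates draw from `N(mu(w), sigma2_y(w))`. Contaminated replicates have
#' extra DNA `lambda ~ N(mean, sd^2)` (truncated positive) added to `w`
#' before evaluating both the mean and the variance. Inhibited replicates
#' behave as if the concentration were `inhibition_multiplier * w` (default
#' 0.1, i.e. 90% lower), again for both mean and variance.
#'
#' @param w positive DNA amounts.
#' @param gamma replicate statuses in `{0, 1, 2}` (recycled).
#' @param alpha1,alpha2 plate coefficients per replicate (recycled).
#' @param a1,a2 CT log-variance regression.
#' @param contamination_spec list with `mean`, `sd`.
#' @param inhibition_multiplier multiplier in (0, 1).
#' @param ct_max censoring limit.
#' @return Numeric vector of CT values with `NA` for censored replicates.
#' @export
simulate_ct <- function(w, gamma, alpha1, alpha2, a1, a2,
                        contamination_spec = list(mean = 3e3, sd = 100),
                        inhibition_multiplier = 0.1, ct_max = 40) {
  if (any(!is.finite(w)) || any(w <= 0)) stop("w must be finite and positive")
  nn <- length(w)
  gamma <- rep_len(gamma, nn)
  w_eff <- w
  ic <- which(gamma == 1L)
  if (length(ic)) {
    lam <- stats::rnorm(length(ic), contamination_spec$mean,
                        contamination_spec$sd)
    while (any(lam <= 0))  # truncate the contaminant amount to be positive
      lam[lam <= 0] <- stats::rnorm(sum(lam <= 0), contamination_spec$mean,
                                    contamination_spec$sd)
    w_eff[ic] <- w[ic] + lam
  }
  ih <- which(gamma == 2L)
  if (length(ih)) w_eff[ih] <- w[ih] * inhibition_multiplier
  mu <- ct_mean(w_eff, alpha1, alpha2)
  sdy <- sqrt(ct_variance(w_eff, a1, a2))
  ct <- stats::rnorm(nn, mu, sdy)
  ct[ct >= ct_max] <- NA_real_
  ct
}

#' Simulate the plate standards
#'
#' On each of `P` plates, `K_star` replicates of each listed concentration
#' are pushed through the same status mixture and CT draw as environmental
#' replicates.
#'
#' @param P number of plates.
#' @param standards_spec list with `concentrations`, `K_star`.
#' @param alpha1,alpha2 per-plate coefficient vectors (length `P`).
#' @param a1,a2 CT log-variance regression.
#' @param p_c,p_h mixture probabilities.
#' @param contamination_spec,inhibition_multiplier,ct_max as [simulate_ct()].
#' @return List with `standards` (data.frame `plate`, `standard_id`,
#'   `concentration`, `ct`) and `gamma_star` (true statuses).
#' @export
simulate_standards <- function(P, standards_spec, alpha1, alpha2, a1, a2,
                               p_c, p_h,
                               contamination_spec = list(mean = 3e3, sd = 100),
                               inhibition_multiplier = 0.1, ct_max = 40) {
  conc <- standards_spec$concentrations
  K_star <- standards_spec$K_star
  std <- expand.grid(rep_id = seq_len(K_star), concentration = conc,
                     plate = seq_len(P))
  std <- std[order(std$plate, std$concentration, std$rep_id), ]
  gam <- simulate_replicate_status(p_c, p_h, nrow(std))
  ct <- simulate_ct(std$concentration, gam, alpha1[std$plate],
                    alpha2[std$plate], a1, a2, contamination_spec,
                    inhibition_multiplier, ct_max)
  list(standards = data.frame(plate = std$plate,
                              standard_id = seq_len(nrow(std)),
                              concentration = std$concentration, ct = ct),
       gamma_star = gam)
}

#' Simulate a complete synthetic survey
#'
#' Draws covariates, plate standard-curve coefficients, the availability and
#' collection stages, replicate statuses and CT values, and the standards,
#' returning the observable dataset alongside the generating truth. The
#' configuration seed fully determines the output; each stage uses its own
#' sub-stream so that design changes at one stage do not perturb draws at
#' earlier stages.
#'
#' @param config an [sim_config()] object.
#' @return List with `dataset` (an `edna_survey`), `latent` (list `l`, `v`,
#'   `gamma`, `gamma_star`) and `params` (the true parameters with realised
#'   per-plate `alpha1`, `alpha2` and per-site `rho`).
#' @export
simulate_survey <- function(config) {
  stopifnot(inherits(config, "edna_sim_config"))
  d <- config$design
  p <- config$params
  cs <- config$covariate_spec
  n <- d$n_sites; T <- d$n_times; nT <- n * T
  samples <- d$samples
  S <- nrow(samples)
  seed <- config$seed

  # stage 1: covariates
  set.seed(.sub_seed(seed, 1L))
  draw_cov <- function(n_rows, n_cont, n_bin) {
    m <- matrix(0, n_rows, n_cont + n_bin)
    if (n_cont) m[, seq_len(n_cont)] <- stats::rnorm(n_rows * n_cont)
    if (n_bin) m[, n_cont + seq_len(n_bin)] <-
        stats::rbinom(n_rows * n_bin, 1L, 0.5)
    colnames(m) <- c(if (n_cont) paste0("xc", seq_len(n_cont)),
                     if (n_bin) paste0("xb", seq_len(n_bin)))
    m
  }
  Xb <- draw_cov(nT, cs$n_site_continuous, cs$n_site_binary)
  Xw <- draw_cov(S, cs$n_sample_continuous, cs$n_sample_binary)

  # stage 2: plate coefficients and site AR rates
  set.seed(.sub_seed(seed, 2L))
  pc_spec <- config$plate_coef_spec
  alpha1 <- stats::rnorm(d$n_plates, pc_spec$mean1, sqrt(pc_spec$var1))
  alpha2 <- stats::rnorm(d$n_plates, pc_spec$mean2, sqrt(pc_spec$var2))
  rho <- rep_len(p$rho, n)

  # stage 3: availability
  set.seed(.sub_seed(seed, 3L))
  l <- simulate_availability(n, T, Xb, p$beta_b0, p$beta_b, rho,
                             p$tau2, p$tau2_1)

  # stage 4: collection
  set.seed(.sub_seed(seed, 4L))
  v <- simulate_collection(l, samples, Xw, p$beta_w, p$sigma2)

  # stage 5: replicate statuses; stage 6: CT values
  rep_tab <- samples[rep(seq_len(S), samples$K), c("site", "time", "sample",
                                                   "plate")]
  rep_tab$replicate <- unlist(lapply(samples$K, seq_len))
  rownames(rep_tab) <- NULL
  set.seed(.sub_seed(seed, 5L))
  gam <- simulate_replicate_status(p$p_c, p$p_h, nrow(rep_tab))
  set.seed(.sub_seed(seed, 6L))
  rs <- rep(seq_len(S), samples$K)
  rep_tab$ct <- simulate_ct(exp(v[rs]), gam, alpha1[rep_tab$plate],
                            alpha2[rep_tab$plate], p$a1, p$a2,
                            config$contamination_spec,
                            config$inhibition_multiplier, d$ct_max)

  # stage 7: standards
  set.seed(.sub_seed(seed, 7L))
  stds <- simulate_standards(d$n_plates, config$standards_spec, alpha1,
                             alpha2, p$a1, p$a2, p$p_c, p$p_h,
                             config$contamination_spec,
                             config$inhibition_multiplier, d$ct_max)

  site_cov <- data.frame(site = rep(seq_len(n), T),
                         time = rep(seq_len(T), each = n), Xb,
                         check.names = FALSE)
  sample_cov <- data.frame(samples[c("site", "time", "sample")], Xw,
                           check.names = FALSE)
  dataset <- survey_dataset(d,
                            rep_tab[c("site", "time", "sample", "replicate",
                                      "plate", "ct")],
                            site_cov, sample_cov, stds$standards)
  truth <- p
  truth$alpha1 <- alpha1
  truth$alpha2 <- alpha2
  truth$rho <- rho
  list(dataset = dataset,
       latent = list(l = l, v = v, gamma = gam,
                     gamma_star = stds$gamma_star),
       params = truth)
}
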