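#' Model parameter container
#'
#' Collects every top-level unknown of the three-stage model plus the fixed
#' constants `sigma_c` (truncated-normal scale for contaminated/inhibited
#' replicates) and `ct_max`. Parameters:
#' \describe{
#'   \item{availability}{`beta_b0` (initial mean log-DNA), `beta_b` (site
#'     covariate coefficients), `rho` (per-site AR(1) rates), `rho0`,
#'     `sigma2_rho` (their hierarchical mean and variance), `tau2` (process
#'     noise), `tau2_1` (between-site variance at the first occasion).}
#'   \item{collection}{`beta_w` (sample covariate coefficients), `sigma2`
#'     (between-sample noise).}
#'   \item{analysis}{per-plate standard-curve coefficients `alpha1`, `alpha2`
#'     with hierarchical means `alpha1_0`, `alpha2_0` and shared variance
#'     `sigma2_alpha`; log-variance regression `a1`, `a2` (heteroscedastic CT
#'     noise); constant CT variance `sigma2_P` (used only by the
#'     `"const_var"` variant); mixture probabilities `p_c` (contamination)
#'     and `p_h` (inhibition), constrained by `p_c + p_h < 0.5`.}
#' }
#'
#' @param beta_b0,beta_b,beta_w,rho,rho0,sigma2_rho,tau2,tau2_1,sigma2 see
#'   Details.
#' @param alpha1,alpha2,alpha1_0,alpha2_0,sigma2_alpha,a1,a2,sigma2_P see
#'   Details.
#' @param p_c,p_h mixture probabilities, `p_c + p_h < 0.5`.
#' @param sigma_c fixed truncated-normal sd for contaminated/inhibited
#'   replicates; the default 40 is of the order of a typical `ct_max`.
#' @param ct_max censoring limit in cycles.
#' @return A validated list of class `edna_params`.
#' @export
model_parameters <- function(beta_b0 = 0, beta_b = numeric(),
                             beta_w = numeric(), rho = 1, rho0 = 1,
                             sigma2_rho = 0.01, tau2 = 1, tau2_1 = 1,
                             sigma2 = 1, alpha1 = 44, alpha2 = -1.7,
                             alpha1_0 = 44, alpha2_0 = -1.7,
                             sigma2_alpha = 0.1, a1 = 0.2, a2 = -0.25,
                             sigma2_P = 1, p_c = 0, p_h = 0, sigma_c = 40,
                             ct_max = 40) {
  p <- list(beta_b0 = beta_b0, beta_b = as.numeric(beta_b),
            beta_w = as.numeric(beta_w), rho = as.numeric(rho), rho0 = rho0,
            sigma2_rho = sigma2_rho, tau2 = tau2, tau2_1 = tau2_1,
            sigma2 = sigma2, alpha1 = as.numeric(alpha1),
            alpha2 = as.numeric(alpha2), alpha1_0 = alpha1_0,
            alpha2_0 = alpha2_0, sigma2_alpha = sigma2_alpha, a1 = a1,
            a2 = a2, sigma2_P = sigma2_P, p_c = p_c, p_h = p_h,
            sigma_c = sigma_c, ct_max = ct_max)
  class(p) <- "edna_params"
  .check_params(p)
  p
}

.check_params <- function(p) {
  pos <- c("sigma2_rho", "tau2", "tau2_1", "sigma2", "sigma2_alpha",
           "sigma2_P", "sigma_c", "ct_max")
  for (f in pos)
    if (!is.numeric(p[[f]]) || p[[f]] <= 0)
      stop(sprintf("parameter %s must be positive", f))
  if (p$p_c < 0 || p$p_h < 0 || p$p_c + p$p_h >= 0.5)
    stop("mixture probabilities must satisfy p_c, p_h >= 0 and p_c + p_h < 0.5")
  invisible(p)
}

#' Model variants for the simulation-study comparison
#'
#' `"full"` is the complete model; `"const_var"` replaces the log-linear CT
#' variance by a single constant variance `sigma2_P` (ignoring
#' heteroscedasticity); `"no_mixture"` fixes `p_c = p_h = 0` (ignoring
#' contamination and inhibition).
#'
#' @param tag one of `"full"`, `"const_var"`, `"no_mixture"`.
#' @return A list of class `edna_variant`.
#' @export
model_variant <- function(tag = c("full", "const_var", "no_mixture")) {
  tag <- match.arg(tag)
  structure(list(tag = tag), class = "edna_variant")
}

.as_variant <- function(variant) {
  if (inherits(variant, "edna_variant")) variant else model_variant(variant)
}

#' Expected CT value for a given DNA amount
#'
#' The plate standard curve: `mu = alpha1 + alpha2 * log(w)` with the natural
#' logarithm. `alpha2` is negative in practice (more DNA amplifies earlier).
#'
#' @param w DNA amount (strictly positive, natural units).
#' @param alpha1,alpha2 plate intercept and slope.
#' @return Expected CT in cycles.
#' @export
ct_mean <- function(w, alpha1, alpha2) {
  if (any(w <= 0)) stop("w must be strictly positive")
  alpha1 + alpha2 * log(w)
}

#' Heteroscedastic CT variance
#'
#' Log-linear variance model `log(sigma2_y(w)) = a1 + a2 * log(w)`
#' (Cook-Weisberg score form). With `a2 < 0` the CT spread grows as the
#' concentration shrinks, the pattern seen in qPCR standards.
#'
#' @param w DNA amount (strictly positive).
#' @param a1,a2 log-variance intercept and slope.
#' @return Variance of the CT value (cycles squared).
#' @export
ct_variance <- function(w, a1, a2) {
  if (any(w <= 0)) stop("w must be strictly positive")
  exp(a1 + a2 * log(w))
}

# CT sd per analysis row given log-amount, the variance regression and the
# variant; gamma != 0 rows use sigma_c regardless of variant.
.ct_sd0 <- function(logw, a1, a2, variant_tag, sigma2_P) {
  if (variant_tag == "const_var") rep(sqrt(sigma2_P), length(logw))
  else exp((a1 + a2 * logw) / 2)
}

# Component log-density for the gamma = 0 (unaffected) branch on a full
# vector: normal with heteroscedastic sd, censored at ct_max.
.ll_g0 <- function(ct, cens, mu, sdy, ct_max) {
  out <- numeric(length(mu))
  if (any(cens)) {
    o <- !cens
    out[o] <- .ldnorm(ct[o], mu[o], if (length(sdy) == 1L) sdy else sdy[o])
    out[cens] <- stats::pnorm(ct_max, mu[cens],
                              if (length(sdy) == 1L) sdy else sdy[cens],
                              lower.tail = FALSE, log.p = TRUE)
  } else out <- .ldnorm(ct, mu, sdy)
  out
}

# gamma = 1 (contaminated): normal truncated to (0, mu); early amplification.
.ll_g1 <- function(ct, cens, mu, sigma_c, ct_max) {
  # truncation normaliser: P(0 < X < mu) with X ~ N(mu, sigma_c^2) = 1/2 -
  # Phi(-mu / sigma_c); empty support (mu <= 0) yields -Inf
  lp0 <- stats::pnorm(0, mu, sigma_c, log.p = TRUE)
  logZ <- .logdiffexp(log(0.5), lp0)
  out <- rep(-Inf, length(mu))
  o <- !cens
  ok <- o & !is.na(ct) & ct > 0 & ct < mu & is.finite(logZ)
  if (any(ok))
    out[ok] <- .ldnorm(ct[ok], mu[ok],
                       if (length(sigma_c) == 1L) sigma_c else sigma_c[ok]) -
      logZ[ok]
  # censoring mass: the part of (0, mu) at or beyond ct_max
  up <- cens & mu > ct_max & is.finite(logZ)
  if (any(up)) {
    s <- if (length(sigma_c) == 1L) rep_len(sigma_c, length(mu)) else sigma_c
    out[up] <- .logdiffexp(log(0.5),
                           stats::pnorm(ct_max, mu[up], s[up],
                                        log.p = TRUE)) - logZ[up]
  }
  out
}

# gamma = 2 (inhibited): normal truncated to (mu, Inf); normaliser 1/2.
.ll_g2 <- function(ct, cens, mu, sigma_c, ct_max) {
  out <- rep(-Inf, length(mu))
  o <- !cens
  ok <- o & !is.na(ct) & ct > mu
  if (any(ok))
    out[ok] <- .ldnorm(ct[ok], mu[ok],
                       if (length(sigma_c) == 1L) sigma_c else sigma_c[ok]) +
      log(2)
  if (any(cens)) {
    ce_hi <- cens & mu >= ct_max
    out[ce_hi] <- 0                     # whole support is beyond ct_max
    ce_lo <- cens & mu < ct_max
    if (any(ce_lo)) {
      s <- if (length(sigma_c) == 1L) rep_len(sigma_c, length(mu)) else sigma_c
      out[ce_lo] <- stats::pnorm(ct_max, mu[ce_lo], s[ce_lo],
                                 lower.tail = FALSE, log.p = TRUE) + log(2)
    }
  }
  out
}

# Core vectorised component log-density. ct may be NA (censored); gamma in
# {0,1,2} (scalar or full vector). Returns the log-density for observed rows
# and the log censoring mass for NA rows, with each component a proper law on
# (-Inf, ct_max) u {censored}. Delegates to the compiled kernel; the pure-R
# reference implementation below stays as the documented contract.
.comp_ll <- function(ct, mu, sdy, gamma, sigma_c, ct_max) {
  nn <- length(mu)
  if (length(ct) != nn) ct <- rep_len(ct, nn)
  if (length(sigma_c) == 1L)
    return(.comp_ll_cpp(as.numeric(ct), as.numeric(mu), as.numeric(sdy),
                        as.integer(gamma), sigma_c, ct_max))
  .comp_ll_r(ct, mu, sdy, gamma, sigma_c, ct_max)
}

.comp_ll_r <- function(ct, mu, sdy, gamma, sigma_c, ct_max) {
  nn <- length(mu)
  if (length(ct) != nn) ct <- rep_len(ct, nn)
  cens <- is.na(ct)
  if (length(gamma) > 1L && !any(gamma != 0L)) gamma <- 0L
  if (length(gamma) == 1L) {
    return(switch(as.character(gamma),
                  "0" = .ll_g0(ct, cens, mu, sdy, ct_max),
                  "1" = .ll_g1(ct, cens, mu, sigma_c, ct_max),
                  "2" = .ll_g2(ct, cens, mu, sigma_c, ct_max)))
  }
  if (length(sdy) == 1L) sdy <- rep_len(sdy, nn)
  out <- numeric(nn)
  i0 <- which(gamma == 0L)
  if (length(i0))
    out[i0] <- .ll_g0(ct[i0], cens[i0], mu[i0], sdy[i0], ct_max)
  i1 <- which(gamma == 1L)
  if (length(i1))
    out[i1] <- .ll_g1(ct[i1], cens[i1], mu[i1],
                      if (length(sigma_c) == 1L) sigma_c else sigma_c[i1],
                      ct_max)
  i2 <- which(gamma == 2L)
  if (length(i2))
    out[i2] <- .ll_g2(ct[i2], cens[i2], mu[i2],
                      if (length(sigma_c) == 1L) sigma_c else sigma_c[i2],
                      ct_max)
  out
}

#' Log-density of one CT observation under a single mixture component
#'
#' For an observed CT below `ct_max`, the log of the component density: a
#' normal with heteroscedastic variance for an unaffected replicate
#' (`gamma = 0`), a normal with scale `sigma_c` truncated to `(0, mu)` for a
#' contaminated one (`gamma = 1`), or truncated to `(mu, Inf)` for an
#' inhibited one (`gamma = 2`). For a censored CT (`ct = NA`) the log of the
#' renormalised mass the component places on `[ct_max, Inf)`, so that each
#' component is a proper law on `(-Inf, ct_max)` together with the censoring
#' atom.
#'
#' @param ct CT value in cycles, or `NA` for censored.
#' @param w DNA amount in the replicate (positive).
#' @param gamma replicate status, 0/1/2.
#' @param alpha1,alpha2 plate standard-curve coefficients.
#' @param a1,a2 CT log-variance regression coefficients.
#' @param sigma_c truncated-normal scale for affected replicates.
#' @param ct_max censoring limit.
#' @param variant model variant (tag or [model_variant()]).
#' @param sigma2_P constant CT variance, used when `variant = "const_var"`.
#' @return Log-density (observed) or log-probability (censored); vectorised.
#'   The density is evaluable over the whole real line below `ct_max` (so
#'   the component laws can be integrated); the truncated components return
#'   `-Inf` outside their support.
#' @export
replicate_component_loglik <- function(ct, w, gamma, alpha1, alpha2, a1, a2,
                                       sigma_c, ct_max, variant = "full",
                                       sigma2_P = 1) {
  variant <- .as_variant(variant)
  if (any(w <= 0) || any(!is.finite(w))) stop("w must be finite and positive")
  if (variant$tag == "no_mixture" && any(gamma != 0L))
    stop("no_mixture variant only permits gamma = 0")
  if (any(!is.na(ct) & ct >= ct_max))
    stop("observed ct must lie below ct_max (use NA for censored)")
  nn <- max(length(ct), length(w), length(gamma))
  mu <- rep_len(ct_mean(w, alpha1, alpha2), nn)
  sdy <- rep_len(.ct_sd0(log(w), a1, a2, variant$tag, sigma2_P), nn)
  .comp_ll(ct, mu, sdy, if (length(gamma) == 1L) gamma else
    rep_len(as.integer(gamma), nn), sigma_c, ct_max)
}

#' Marginal log-density of one CT observation under the mixture
#'
#' Mixes the three component log-densities with weights
#' `(1 - p_c - p_h, p_c, p_h)` by log-sum-exp. With `p_c = p_h = 0` (or the
#' `"no_mixture"` variant) this equals the `gamma = 0` component exactly.
#'
#' @inheritParams replicate_component_loglik
#' @param p_c,p_h contamination and inhibition probabilities.
#' @return Marginal log-density; vectorised.
#' @export
replicate_marginal_loglik <- function(ct, w, p_c, p_h, alpha1, alpha2, a1, a2,
                                      sigma_c, ct_max, variant = "full",
                                      sigma2_P = 1) {
  variant <- .as_variant(variant)
  if (p_c < 0 || p_h < 0 || p_c + p_h >= 0.5)
    stop("require p_c, p_h >= 0 and p_c + p_h < 0.5")
  if (variant$tag == "no_mixture") { p_c <- 0; p_h <- 0 }
  L0 <- replicate_component_loglik(ct, w, 0L, alpha1, alpha2, a1, a2,
                                   sigma_c, ct_max,
                                   model_variant(if (variant$tag == "no_mixture") "full" else variant$tag),
                                   sigma2_P)
  if (p_c == 0 && p_h == 0) return(L0)
  mu <- ct_mean(w, alpha1, alpha2)
  if (length(mu) != length(L0)) mu <- rep_len(mu, length(L0))
  L1 <- .comp_ll(rep_len(ct, length(L0)), mu, 1, 1L, sigma_c, ct_max)
  L2 <- .comp_ll(rep_len(ct, length(L0)), mu, 1, 2L, sigma_c, ct_max)
  .logsumexp_rows(cbind(log1p(-p_c - p_h) + L0,
                        log(p_c) + L1,
                        log(p_h) + L2))
}

# Covariate linear predictor as an n x T matrix; xb is nT x q in occasion
# order (t - 1) * n + i.
.eta_matrix <- function(xb, beta_b, n, T) {
  if (ncol(xb) == 0L || length(beta_b) == 0L) return(matrix(0, n, T))
  matrix(drop(xb %*% beta_b), n, T)
}

#' Log-density of the latent availability process
#'
#' Sums the AR(1) state-space log-density of the site-by-time log-DNA matrix
#' `l`: at the first occasion `l[i,1] ~ N(beta_b0 + X^b[i,1] beta_b, tau2_1)`,
#' and for `t > 1`
#' `l[i,t] ~ N(rho[i] (l[i,t-1] - X^b[i,t-1] beta_b) + X^b[i,t] beta_b, tau2)`
#' (the AR(1) acts on the covariate-detrended process).
#'
#' @param l `n x T` matrix of log-DNA availability.
#' @param X_b site covariates: `NULL`, or an `(n*T) x q` matrix in occasion
#'   order (`(t-1)*n + i`), or an `n x T x q` array.
#' @param beta_b0,beta_b,rho,tau2,tau2_1 availability parameters (`rho` is
#'   recycled to `n` sites).
#' @return Scalar log-density.
#' @export
availability_loglik <- function(l, X_b, beta_b0, beta_b, rho, tau2, tau2_1) {
  if (tau2 <= 0 || tau2_1 <= 0) stop("variances must be positive")
  l <- as.matrix(l)
  n <- nrow(l); T <- ncol(l)
  xb <- .coerce_xb(X_b, n, T)
  eta <- .eta_matrix(xb, beta_b, n, T)
  rho <- rep_len(rho, n)
  ll <- sum(.ldnorm(l[, 1L], beta_b0 + eta[, 1L], sqrt(tau2_1)))
  if (T > 1L) {
    prev <- l[, -T, drop = FALSE] - eta[, -T, drop = FALSE]
    m <- rho * prev + eta[, -1L, drop = FALSE]
    ll <- ll + sum(.ldnorm(l[, -1L, drop = FALSE], m, sqrt(tau2)))
  }
  ll
}

.coerce_xb <- function(X_b, n, T) {
  if (is.null(X_b)) return(matrix(0, n * T, 0))
  if (is.array(X_b) && length(dim(X_b)) == 3L) {
    q <- dim(X_b)[3L]
    return(matrix(X_b, n * T, q))
  }
  as.matrix(X_b)
}

#' Log-density of the collection stage
#'
#' Each sample's log-DNA is normal around the site availability plus sample
#' covariate effects: `v[s] ~ N(l[i(s), t(s)] + X^w[s] beta_w, sigma2)`.
#'
#' @param v numeric vector of sample log-DNA, aligned with `samples`.
#' @param l `n x T` availability matrix.
#' @param samples data.frame with columns `site` and `time`, one row per
#'   sample, aligned with `v`.
#' @param X_w `NULL` or a matrix of sample covariates with `length(v)` rows.
#' @param beta_w,sigma2 collection parameters.
#' @return Scalar log-density.
#' @export
collection_loglik <- function(v, l, samples, X_w, beta_w, sigma2) {
  if (sigma2 <= 0) stop("sigma2 must be positive")
  l <- as.matrix(l)
  occ <- (samples$time - 1L) * nrow(l) + samples$site
  m <- as.vector(l)[occ]
  if (!is.null(X_w) && ncol(as.matrix(X_w)) > 0L && length(beta_w))
    m <- m + drop(as.matrix(X_w) %*% beta_w)
  sum(.ldnorm(v, m, sqrt(sigma2)))
}

#' Log-density of the parameter hierarchies
#'
#' Site AR(1) rates `rho[i] ~ N(rho0, sigma2_rho)` and plate standard-curve
#' coefficients `alpha1[p] ~ N(alpha1_0, sigma2_alpha)`,
#' `alpha2[p] ~ N(alpha2_0, sigma2_alpha)`; intercepts and slopes share the
#' same hierarchical variance.
#'
#' @param rho,rho0,sigma2_rho site AR(1) hierarchy.
#' @param alpha1,alpha2,alpha1_0,alpha2_0,sigma2_alpha plate hierarchy.
#' @return Scalar log-density.
#' @export
hierarchy_loglik <- function(rho, rho0, sigma2_rho, alpha1, alpha2,
                             alpha1_0, alpha2_0, sigma2_alpha) {
  if (sigma2_rho <= 0 || sigma2_alpha <= 0)
    stop("hierarchy variances must be positive")
  sum(.ldnorm(rho, rho0, sqrt(sigma2_rho))) +
    sum(.ldnorm(alpha1, alpha1_0, sqrt(sigma2_alpha))) +
    sum(.ldnorm(alpha2, alpha2_0, sqrt(sigma2_alpha)))
}

#' Default weakly-informative priors
#'
#' Regression-type coefficients (`beta_b0`, `beta_b`, `beta_w`, `rho0`, `a1`,
#' `a2`) get Normal(0, 10^2); the standard-curve hierarchical means get
#' Normal(40, 10^2) for the intercept and Normal(0, 10^2) for the slope; every
#' standard deviation (`tau`, `tau_1`, `sigma`, `sigma_rho`, `sigma_alpha`,
#' `sigma_P`) gets half-Normal(0, 5^2) on the sd scale; `(p_c, p_h)` is
#' uniform on the constrained simplex `p_c, p_h >= 0, p_c + p_h < 0.5`.
#' Any element can be overridden by name.
#'
#' @param ... named overrides, each a list with `mean` and `sd` (for normal
#'   priors) or `scale` (for half-normal sd priors).
#' @return A list of class `edna_priors`.
#' @export
default_priors <- function(...) {
  pr <- list(
    beta_b0 = list(mean = 0, sd = 10),
    beta_b = list(mean = 0, sd = 10),
    beta_w = list(mean = 0, sd = 10),
    rho0 = list(mean = 0, sd = 10),
    a1 = list(mean = 0, sd = 10),
    a2 = list(mean = 0, sd = 10),
    alpha1_0 = list(mean = 40, sd = 10),
    alpha2_0 = list(mean = 0, sd = 10),
    sd = list(scale = 5)  # shared half-normal scale for all sd parameters
  )
  over <- list(...)
  for (nm in names(over)) pr[[nm]] <- over[[nm]]
  structure(pr, class = "edna_priors")
}

# Half-normal log-density on the sd scale.
.lhalfnorm <- function(sd_value, scale) {
  if (any(sd_value <= 0)) return(-Inf)
  sum(.ldnorm(sd_value, 0, scale) + log(2))
}

# Total prior log-density of a parameter set (sd parameters on the sd scale;
# (p_c, p_h) uniform on the constrained simplex, contributing a constant).
.prior_ll <- function(p, priors, variant_tag) {
  nm <- function(x, spec) sum(.ldnorm(x, spec$mean, spec$sd))
  ll <- nm(p$beta_b0, priors$beta_b0) + nm(p$beta_b, priors$beta_b) +
    nm(p$beta_w, priors$beta_w) + nm(p$rho0, priors$rho0) +
    nm(p$alpha1_0, priors$alpha1_0) + nm(p$alpha2_0, priors$alpha2_0) +
    .lhalfnorm(sqrt(p$tau2), priors$sd$scale) +
    .lhalfnorm(sqrt(p$tau2_1), priors$sd$scale) +
    .lhalfnorm(sqrt(p$sigma2), priors$sd$scale) +
    .lhalfnorm(sqrt(p$sigma2_rho), priors$sd$scale) +
    .lhalfnorm(sqrt(p$sigma2_alpha), priors$sd$scale)
  if (variant_tag == "const_var") {
    ll <- ll + .lhalfnorm(sqrt(p$sigma2_P), priors$sd$scale)
  } else {
    ll <- ll + nm(p$a1, priors$a1) + nm(p$a2, priors$a2)
  }
  ll
}

# Flatten a dataset into index vectors for the likelihood and the sampler.
.pack <- function(dataset) {
  d <- dataset$design
  n <- d$n_sites; T <- d$n_times; nT <- n * T
  samples <- d$samples
  so <- (samples$time - 1L) * n + samples$site     # occasion of each sample
  S <- nrow(samples)
  rep <- dataset$replicates
  # replicate -> sample index (samples are in canonical order)
  key_s <- paste(samples$site, samples$time, samples$sample)
  rs <- match(paste(rep$site, rep$time, rep$sample), key_s)
  std <- dataset$standards
  list(n = n, T = T, nT = nT, S = S, R = nrow(rep),
       n_plates = d$n_plates, ct_max = d$ct_max,
       samples = samples, so = so, rs = rs,
       rp = rep$plate, ct = rep$ct, cens = is.na(rep$ct),
       sp = std$plate, s_logw = log(std$concentration), s_ct = std$ct,
       s_cens = is.na(std$ct), n_std = nrow(std),
       Xb = .xb_matrix(dataset), Xw = .xw_matrix(dataset),
       site_of_occ = rep(seq_len(n), T), time_of_occ = rep(seq_len(T), each = n))
}

#' Joint log-posterior of the full model state
#'
#' Sums the availability, collection and hierarchy log-densities, the CT
#' likelihood of every environmental replicate and standard (standards use
#' their known amounts; both share the mixture), and the prior log-densities.
#' If `latent$gamma` (and `latent$gamma_star` for standards) is supplied the
#' CT terms condition on those indicators; otherwise the mixture is
#' marginalised. Returns `-Inf` when `p_c + p_h >= 0.5` or a probability is
#' negative.
#'
#' @param params an `edna_params` list (see [model_parameters()]); `alpha1`,
#'   `alpha2` must have one entry per plate.
#' @param latent list with `l` (`n x T` matrix), `v` (vector over samples),
#'   and optionally `gamma` (env replicates) and `gamma_star` (standards).
#' @param dataset an `edna_survey`.
#' @param priors an `edna_priors` list.
#' @param variant model variant tag or object.
#' @return Scalar log-posterior density (unnormalised).
#' @export
joint_log_posterior <- function(params, latent, dataset,
                                priors = default_priors(),
                                variant = "full") {
  variant <- .as_variant(variant)
  p <- params
  if (p$p_c < 0 || p$p_h < 0 || p$p_c + p$p_h >= 0.5) return(-Inf)
  pk <- .pack(dataset)
  l <- as.matrix(latent$l); v <- latent$v
  stopifnot(nrow(l) == pk$n, ncol(l) == pk$T, length(v) == pk$S)

  ll <- availability_loglik(l, pk$Xb, p$beta_b0, p$beta_b, p$rho, p$tau2,
                            p$tau2_1) +
    collection_loglik(v, l, pk$samples, pk$Xw, p$beta_w, p$sigma2) +
    hierarchy_loglik(p$rho, p$rho0, p$sigma2_rho, p$alpha1, p$alpha2,
                     p$alpha1_0, p$alpha2_0, p$sigma2_alpha)

  ct_all <- c(pk$ct, pk$s_ct)
  logw_all <- c(v[pk$rs], pk$s_logw)
  plate_all <- c(pk$rp, pk$sp)
  mu <- p$alpha1[plate_all] + p$alpha2[plate_all] * logw_all
  sdy <- .ct_sd0(logw_all, p$a1, p$a2, variant$tag, p$sigma2_P)
  gam <- latent$gamma
  gam_star <- latent$gamma_star
  use_mixture <- variant$tag != "no_mixture"
  if (!use_mixture || (is.null(gam) && p$p_c == 0 && p$p_h == 0)) {
    ll <- ll + sum(.comp_ll(ct_all, mu, sdy, 0L, p$sigma_c, pk$ct_max))
  } else if (!is.null(gam)) {
    if (is.null(gam_star)) gam_star <- rep(0L, pk$n_std)
    g <- c(gam, gam_star)
    ll <- ll + sum(.comp_ll(ct_all, mu, sdy, g, p$sigma_c, pk$ct_max))
    nc <- tabulate(g + 1L, 3L)
    ll <- ll + nc[1L] * log1p(-p$p_c - p$p_h) +
      (if (nc[2L]) nc[2L] * log(p$p_c) else 0) +
      (if (nc[3L]) nc[3L] * log(p$p_h) else 0)
  } else {
    L0 <- .comp_ll(ct_all, mu, sdy, 0L, p$sigma_c, pk$ct_max)
    L1 <- .comp_ll(ct_all, mu, 1, 1L, p$sigma_c, pk$ct_max)
    L2 <- .comp_ll(ct_all, mu, 1, 2L, p$sigma_c, pk$ct_max)
    ll <- ll + sum(.logsumexp_rows(cbind(
      log1p(-p$p_c - p$p_h) + L0,
      (if (p$p_c > 0) log(p$p_c) else -Inf) + L1,
      (if (p$p_h > 0) log(p$p_h) else -Inf) + L2)))
  }
  ll + .prior_ll(p, priors, variant$tag)
}
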