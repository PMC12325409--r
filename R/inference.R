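#' MCMC sampler settings
#'
#' Defaults are sized for case-study data (3 chains of 50,000 iterations,
#' half burn-in, thinning 5). The `"test"` preset is a scaled-down setting
#' for simulation studies and unit tests.
#'
#' @param n_iter iterations per chain (including burn-in).
#' @param n_burnin burn-in iterations discarded per chain
#'   (`n_iter > n_burnin >= 0`).
#' @param thin thinning interval for retained draws.
#' @param n_chains number of chains (run sequentially, seeded independently).
#' @param seed integer seed; all chain randomness derives from it.
#' @param adapt_interval Robbins-Monro step-size adaptation batch length;
#'   adaptation targets 0.44 acceptance and is frozen after burn-in so the
#'   retained chains are Markov.
#' @param blocks `NULL` to update every parameter block, or a character
#'   subset of `c("gamma", "p", "v", "l", "beta_b", "rho", "var_avail",
#'   "sigma2", "beta_w", "alpha", "alpha_hier", "ct_var")`; blocks left out
#'   stay at their initial values (useful for conditional-sampler tests).
#' @param save_gamma store full per-iteration draws of the replicate status
#'   indicators (memory-heavy); posterior status frequencies are always
#'   accumulated.
#' @param jitter_init sd of the chain-specific jitter added to the initial
#'   latent state so multiple chains do not start identically.
#' @param preset `"case"` (the defaults) or `"test"` (1,500 iterations, 600
#'   burn-in, thin 2, single chain).
#' @param verbose print progress.
#' @return A list of class `edna_mcmc_control`.
#' @export
mcmc_control <- function(n_iter = 50000, n_burnin = 25000, thin = 5,
                         n_chains = 3, seed = 1L, adapt_interval = 50,
                         blocks = NULL, save_gamma = FALSE,
                         jitter_init = 0.1, preset = NULL, verbose = FALSE) {
  if (identical(preset, "test")) {
    n_iter <- 1500; n_burnin <- 600; thin <- 2; n_chains <- 1
  }
  stopifnot(n_iter > n_burnin, n_burnin >= 0, thin >= 1, n_chains >= 1)
  structure(list(n_iter = as.integer(n_iter),
                 n_burnin = as.integer(n_burnin), thin = as.integer(thin),
                 n_chains = as.integer(n_chains), seed = as.integer(seed),
                 adapt_interval = as.integer(adapt_interval),
                 blocks = blocks, save_gamma = isTRUE(save_gamma),
                 jitter_init = jitter_init, verbose = isTRUE(verbose)),
            class = "edna_mcmc_control")
}

#' Full-conditional probabilities of the replicate status indicators
#'
#' For each CT observation, the posterior probability of being unaffected,
#' contaminated or inhibited given the parameters and the replicate's DNA
#' amount: weights proportional to `(1 - p_c - p_h) f0`, `p_c f1`, `p_h f2`
#' with `f_g` the component (or censoring-mass) densities.
#'
#' @inheritParams replicate_component_loglik
#' @param p_c,p_h mixture probabilities.
#' @return Matrix with one row per observation and columns
#'   `c("unaffected", "contaminated", "inhibited")`.
#' @export
gamma_fullcond_probs <- function(ct, w, p_c, p_h, alpha1, alpha2, a1, a2,
                                 sigma_c, ct_max, variant = "full",
                                 sigma2_P = 1) {
  variant <- .as_variant(variant)
  mu <- ct_mean(w, alpha1, alpha2)
  sdy <- .ct_sd0(log(w), a1, a2, variant$tag, sigma2_P)
  nn <- length(mu)
  W <- cbind(log1p(-p_c - p_h) +
               .comp_ll(ct, mu, sdy, 0L, sigma_c, ct_max),
             (if (p_c > 0) log(p_c) else -Inf) +
               .comp_ll(ct, mu, sdy, 1L, sigma_c, ct_max),
             (if (p_h > 0) log(p_h) else -Inf) +
               .comp_ll(ct, mu, sdy, 2L, sigma_c, ct_max))
  pr <- exp(W - .logsumexp_rows(W))
  colnames(pr) <- c("unaffected", "contaminated", "inhibited")
  pr
}

#' Gibbs update of the replicate status indicators
#'
#' Draws each indicator from its exact full conditional (see
#' [gamma_fullcond_probs()]). With `p_c = p_h = 0` the indicators remain 0
#' with probability one.
#'
#' @inheritParams gamma_fullcond_probs
#' @return Integer vector of sampled statuses in `{0, 1, 2}`.
#' @export
update_gamma <- function(ct, w, p_c, p_h, alpha1, alpha2, a1, a2, sigma_c,
                         ct_max, variant = "full", sigma2_P = 1) {
  pr <- gamma_fullcond_probs(ct, w, p_c, p_h, alpha1, alpha2, a1, a2,
                             sigma_c, ct_max, variant, sigma2_P)
  u <- stats::runif(nrow(pr))
  (u > pr[, 1L]) + (u > pr[, 1L] + pr[, 2L])
}

#' Joint Metropolis proposal for the mixture probabilities
#'
#' Random-walk proposal for `(p_c, p_h)` with the hard constraint
#' `p_c + p_h < 1 - (p_c + p_h)`: a proposal violating it (or with a negative
#' component) rejects both probabilities outright; otherwise the usual
#' Metropolis ratio for the categorical likelihood of the current status
#' counts is used (the prior is uniform on the constrained simplex).
#'
#' @param p_c,p_h current values (must satisfy the constraint).
#' @param counts integer vector `c(n_unaffected, n_contaminated,
#'   n_inhibited)` of current indicator counts.
#' @param step random-walk sd (shared by both components).
#' @return List with the new `p_c`, `p_h`, logical `accepted` and logical
#'   `constraint_rejected`.
#' @export
propose_probabilities <- function(p_c, p_h, counts, step = 0.01) {
  stopifnot(p_c >= 0, p_h >= 0, p_c + p_h < 0.5)
  prop <- c(p_c, p_h) + stats::rnorm(2L, 0, step)
  if (any(prop < 0) || sum(prop) >= 0.5)
    return(list(p_c = p_c, p_h = p_h, accepted = FALSE,
                constraint_rejected = TRUE))
  llr <- function(pc, ph) {
    counts[1L] * log1p(-pc - ph) +
      (if (counts[2L]) counts[2L] * log(pc) else 0) +
      (if (counts[3L]) counts[3L] * log(ph) else 0)
  }
  d <- llr(prop[1L], prop[2L]) - llr(p_c, p_h)
  if (is.finite(d) && log(stats::runif(1L)) < d)
    list(p_c = prop[1L], p_h = prop[2L], accepted = TRUE,
         constraint_rejected = FALSE)
  else
    list(p_c = p_c, p_h = p_h, accepted = FALSE, constraint_rejected = FALSE)
}

#' Initial MCMC state from the data
#'
#' Standard-curve coefficients are initialised by per-plate ordinary least
#' squares of CT on log-concentration over that plate's uncensored standards
#' (plates with fewer than two distinct uncensored concentrations fall back
#' to the pooled fit). Sample log-DNA `v` is initialised by inverting the
#' plate line at the sample's mean observed CT; samples whose replicates are
#' all censored start at the concentration whose expected CT equals
#' `ct_max`. Site availability starts at the within-occasion mean of `v`,
#' the status indicators at 0, and the mixture probabilities at
#' `(0.01, 0.01)`.
#'
#' @param dataset an `edna_survey`.
#' @param variant model variant.
#' @param seed integer seed (initialisation is deterministic given it).
#' @return List with `params` (an `edna_params`) and `latent`
#'   (`l`, `v`, `gamma`, `gamma_star`).
#' @export
initialize_state <- function(dataset, variant = "full", seed = 1L) {
  variant <- .as_variant(variant)
  pk <- .pack(dataset)
  set.seed(.sub_seed(seed, 99L))
  P <- pk$n_plates

  std_ok <- !pk$s_cens
  pooled <- if (sum(std_ok) >= 2L)
    unname(stats::coef(stats::lm(pk$s_ct[std_ok] ~ pk$s_logw[std_ok])))
  else c(40, -1.5)
  alpha1 <- rep(pooled[1L], P); alpha2 <- rep(pooled[2L], P)
  res <- numeric(0); res_logw <- numeric(0)
  for (p in seq_len(P)) {
    idx <- which(pk$sp == p & std_ok)
    if (length(unique(pk$s_logw[idx])) >= 2L) {
      f <- stats::lm(pk$s_ct[idx] ~ pk$s_logw[idx])
      alpha1[p] <- unname(stats::coef(f)[1L])
      alpha2[p] <- unname(stats::coef(f)[2L])
      res <- c(res, stats::resid(f)); res_logw <- c(res_logw, pk$s_logw[idx])
    }
  }
  if (length(res) >= 4L && length(unique(res_logw)) >= 2L) {
    vf <- unname(stats::coef(stats::lm(log(res^2 + 1e-8) ~ res_logw)))
    a1 <- vf[1L]; a2 <- vf[2L]
    sigma2_P <- max(stats::var(res), 1e-3)
  } else {
    a1 <- 0; a2 <- 0; sigma2_P <- 1
  }
  safe_var <- function(x, floor_) {
    v <- if (length(x) >= 2L) stats::var(as.vector(x)) else NA_real_
    if (!is.finite(v)) floor_ else max(v, floor_)
  }

  # invert the plate line at the per-sample mean observed CT
  ct_for_mean <- ifelse(pk$cens, NA, pk$ct)
  ct_bar <- as.numeric(tapply(ct_for_mean, pk$rs, mean, na.rm = TRUE))
  ct_bar <- ifelse(is.finite(ct_bar), ct_bar, pk$ct_max)
  plate_of_sample <- pk$samples$plate
  v <- (ct_bar - alpha1[plate_of_sample]) / alpha2[plate_of_sample]
  occ_mean <- tapply(v, pk$so, mean)
  lf <- rep(mean(v), pk$nT)
  lf[as.integer(names(occ_mean))] <- as.numeric(occ_mean)
  l <- matrix(lf, pk$n, pk$T)

  rho0 <- 1
  if (pk$T > 1L) {
    x <- as.vector(l[, -pk$T, drop = FALSE]); y <- as.vector(l[, -1L, drop = FALSE])
    if (length(x) >= 2L && stats::var(x) > 1e-8)
      rho0 <- max(min(unname(stats::coef(stats::lm(y ~ x))[2L]), 2), -2)
  }
  tau2 <- if (pk$T > 1L) safe_var(l[, -1L] - l[, -pk$T], 0.1) else 1
  tau2_1 <- safe_var(l[, 1L], 0.1)
  sigma2 <- safe_var(v - lf[pk$so], 0.05)

  mixture <- variant$tag != "no_mixture"
  params <- model_parameters(
    beta_b0 = mean(l[, 1L]),
    beta_b = rep(0, ncol(pk$Xb)), beta_w = rep(0, ncol(pk$Xw)),
    rho = rep(rho0, pk$n), rho0 = rho0, sigma2_rho = 0.1,
    tau2 = tau2, tau2_1 = tau2_1, sigma2 = sigma2,
    alpha1 = alpha1, alpha2 = alpha2,
    alpha1_0 = mean(alpha1), alpha2_0 = mean(alpha2),
    sigma2_alpha = safe_var(c(alpha1 - mean(alpha1),
                              alpha2 - mean(alpha2)), 1e-3),
    a1 = a1, a2 = a2, sigma2_P = sigma2_P,
    p_c = if (mixture) 0.01 else 0, p_h = if (mixture) 0.01 else 0,
    sigma_c = pk$ct_max, ct_max = pk$ct_max)
  list(params = params,
       latent = list(l = l, v = v, gamma = rep(0L, pk$R),
                     gamma_star = rep(0L, pk$n_std)))
}

# All sampler block names, in sweep order.
.all_blocks <- c("gamma", "p", "v", "l", "beta_b", "rho", "var_avail",
                 "sigma2", "beta_w", "alpha", "alpha_hier", "ct_var")

#' Fit the eDNA concentration model by MCMC
#'
#' Metropolis-within-Gibbs sampler: exact categorical Gibbs for the replicate
#' status indicators, a joint random-walk with the rejection constraint for
#' `(p_c, p_h)`, and adaptive single-site random-walk Metropolis for the
#' latent states, regression coefficients, hierarchies and variance
#' parameters. Censored replicates contribute their censoring mass directly
#' (no latent CT imputation). Deterministic given `control$seed`.
#'
#' @param dataset a validated `edna_survey`.
#' @param variant `"full"`, `"const_var"` or `"no_mixture"` (tag or
#'   [model_variant()] object).
#' @param priors an `edna_priors` list, see [default_priors()].
#' @param control an [mcmc_control()] list.
#' @param init optional initial state as returned by [initialize_state()]
#'   (defaults to data-driven initialisation).
#' @return An object of class `edna_fit` with elements `params` (retained
#'   draws, one column per scalar parameter), `l`, `v` (latent draws),
#'   `gamma_prob` (posterior status frequencies per analysis row,
#'   environmental replicates then standards), optionally `gamma`, `chain`
#'   (chain index of each retained draw), `accept` (mean acceptance rate per
#'   block), plus the control, variant and data dimensions.
#' @export
fit_edna <- function(dataset, variant = "full", priors = default_priors(),
                     control = mcmc_control(), init = NULL) {
  variant <- .as_variant(variant)
  viol <- validate_dataset(dataset)
  if (nrow(viol))
    stop("dataset failed validation; first issue: ", viol$message[1L])
  pk <- .pack(dataset)
  blocks <- control$blocks %||% .all_blocks
  mixture <- variant$tag != "no_mixture"
  if (!mixture) blocks <- setdiff(blocks, c("gamma", "p"))
  if (is.null(init)) init <- initialize_state(dataset, variant, control$seed)

  n_keep <- (control$n_iter - control$n_burnin) %/% control$thin
  chains <- lapply(seq_len(control$n_chains), function(ch)
    .run_chain(pk, variant, priors, control, init, chain_id = ch,
               blocks = blocks, n_keep = n_keep))

  draws <- do.call(rbind, lapply(chains, `[[`, "params"))
  l_draws <- do.call(rbind, lapply(chains, `[[`, "l"))
  v_draws <- do.call(rbind, lapply(chains, `[[`, "v"))
  gp <- Reduce(`+`, lapply(chains, `[[`, "gamma_prob")) / length(chains)
  fit <- structure(list(
    params = draws, l = l_draws, v = v_draws, gamma_prob = gp,
    gamma = if (control$save_gamma)
      do.call(rbind, lapply(chains, `[[`, "gamma")) else NULL,
    chain = rep(seq_len(control$n_chains), each = n_keep),
    accept = {
      accs <- lapply(chains, `[[`, "accept")
      out <- accs[[1L]]
      for (nm in names(out))
        out[[nm]] <- Reduce(`+`, lapply(accs, `[[`, nm)) / length(accs)
      out
    },
    variant = variant, control = control, priors = priors,
    dims = list(n = pk$n, T = pk$T, S = pk$S, R = pk$R, n_std = pk$n_std,
                n_plates = pk$n_plates),
    init = init), class = "edna_fit")
  fit
}

#' @export
print.edna_fit <- function(x, ...) {
  cat(sprintf(
    "eDNA model fit (variant: %s): %d retained draws (%d chain%s), %d scalar parameters\n",
    x$variant$tag, nrow(x$params), x$control$n_chains,
    if (x$control$n_chains > 1) "s" else "", ncol(x$params)))
  key <- intersect(c("beta_b0", "tau2", "sigma2", "a1", "a2", "p_c", "p_h"),
                   colnames(x$params))
  print(round(colMeans(x$params[, key, drop = FALSE]), 3))
  invisible(x)
}

# One MCMC chain. Everything heavy is vectorised: the status Gibbs step, the
# sample-level and occasion-level Metropolis updates and the per-plate
# coefficient updates each run as a single vectorised accept/reject.
.run_chain <- function(pk, variant, priors, control, init, chain_id, blocks,
                       n_keep) {
  set.seed(.sub_seed(control$seed, chain_id, 17L))
  vt <- variant$tag
  p <- init$params
  l <- init$latent$l
  v <- init$latent$v
  gam <- c(init$latent$gamma, init$latent$gamma_star)
  if (control$jitter_init > 0 && chain_id > 1L) {
    l <- l + stats::rnorm(length(l), 0, control$jitter_init)
    v <- v + stats::rnorm(length(v), 0, control$jitter_init)
  }
  n <- pk$n; T <- pk$T; nT <- pk$nT; S <- pk$S
  qb <- ncol(pk$Xb); qw <- ncol(pk$Xw)
  P <- pk$n_plates
  ct_a <- c(pk$ct, pk$s_ct)
  plate_a <- c(pk$rp, pk$sp)
  nA <- length(ct_a)
  env <- seq_len(pk$R)
  rs <- pk$rs; so <- pk$so
  sigma_c <- p$sigma_c; ct_max <- pk$ct_max
  lf <- as.vector(l)

  # cached quantities
  eta <- .eta_matrix(pk$Xb, p$beta_b, n, T)      # site linear predictor
  xwb <- if (qw) drop(pk$Xw %*% p$beta_w) else numeric(S)
  mv <- lf[so] + xwb                             # collection means
  logw_a <- c(v[rs], pk$s_logw)

  rl_all <- function(logw, gam_, a1, a2, s2P, alpha1, alpha2) {
    .comp_ll(ct_a, alpha1[plate_a] + alpha2[plate_a] * logw,
             .ct_sd0(logw, a1, a2, vt, s2P), gam_, sigma_c, ct_max)
  }
  avail_terms <- function(lmat, bb0, bb_eta, rho, tau2, tau2_1) {
    # n x T matrix of availability log-density terms
    out <- matrix(0, n, T)
    out[, 1L] <- .ldnorm(lmat[, 1L], bb0 + bb_eta[, 1L], sqrt(tau2_1))
    if (T > 1L) {
      m <- rho * (lmat[, -T, drop = FALSE] - bb_eta[, -T, drop = FALSE]) +
        bb_eta[, -1L, drop = FALSE]
      out[, -1L] <- .ldnorm(lmat[, -1L, drop = FALSE], m, sqrt(tau2))
    }
    out
  }

  # adaptive step sizes (log scale)
  ls <- list(v = rep(log(0.5), S), l = rep(log(0.3), nT),
             rho = rep(log(0.2), n), alpha1 = rep(log(0.1), P),
             alpha2 = rep(log(0.05), P),
             scalars = c(p_jt = log(0.02), beta_b0 = log(0.2),
                         beta_b = log(0.1), beta_w = log(0.05),
                         rho0 = log(0.1), lsig_rho = log(0.3),
                         ltau = log(0.2), ltau1 = log(0.3),
                         lsig = log(0.1), alpha1_0 = log(0.1),
                         alpha2_0 = log(0.05), lsig_alpha = log(0.2),
                         a1 = log(0.1), a2 = log(0.02), lsigP = log(0.1)))
  acc <- list(v = numeric(S), l = numeric(nT), rho = numeric(n),
              alpha1 = numeric(P), alpha2 = numeric(P),
              scalars = numeric(length(ls$scalars)))
  names(acc$scalars) <- names(ls$scalars)
  acc_total <- acc
  n_batch <- 0L

  scalar_mh <- function(name, cur, delta_fn) {
    # generic scalar Metropolis step; delta_fn(prop) returns log ratio
    prop <- cur + exp(ls$scalars[[name]]) * stats::rnorm(1L)
    d <- delta_fn(prop)
    ok <- is.finite(d) && log(stats::runif(1L)) < d
    if (ok) {
      acc$scalars[[name]] <<- acc$scalars[[name]] + 1
      prop
    } else cur
  }

  keep_params <- NULL
  keep_l <- matrix(NA_real_, n_keep, nT)
  keep_v <- matrix(NA_real_, n_keep, S)
  keep_gamma <- if (control$save_gamma) matrix(NA_integer_, n_keep, nA)
  gamma_prob <- matrix(0, nA, 3L)
  kk <- 0L
  do_block <- function(b) b %in% blocks
  adapting <- TRUE

  for (iter in seq_len(control$n_iter)) {
    if (iter > control$n_burnin) adapting <- FALSE

    ## --- replicate status indicators (exact Gibbs) -----------------------
    if (do_block("gamma") && (p$p_c > 0 || p$p_h > 0)) {
      mu_a <- p$alpha1[plate_a] + p$alpha2[plate_a] * logw_a
      sdy_a <- .ct_sd0(logw_a, p$a1, p$a2, vt, p$sigma2_P)
      gam <- .gamma_gibbs_cpp(ct_a, mu_a, sdy_a, sigma_c, ct_max,
                              log1p(-p$p_c - p$p_h), log(p$p_c),
                              log(p$p_h), stats::runif(nA))
    }

    ## --- (p_c, p_h): joint random walk with rejection constraint ---------
    if (do_block("p")) {
      counts <- tabulate(gam + 1L, 3L)
      res <- propose_probabilities(p$p_c, p$p_h, counts,
                                   step = exp(ls$scalars[["p_jt"]]))
      if (res$accepted) acc$scalars[["p_jt"]] <- acc$scalars[["p_jt"]] + 1
      p$p_c <- res$p_c; p$p_h <- res$p_h
    }

    ## --- sample log-DNA v: Metropolis-Hastings with a tailored normal ----
    ## proposal built from the sample's uncensored gamma = 0 replicates
    ## (inverting the plate line, precision-weighted), corrected by the
    ## exact likelihood ratio so censored/affected replicates and the
    ## heteroscedastic variance are honoured.
    if (do_block("v")) {
      al2r <- p$alpha2[pk$rp]
      sdy_env <- .ct_sd0(logw_a[env], p$a1, p$a2, vt, p$sigma2_P)
      use <- (gam[env] == 0L) & !pk$cens
      w_prec <- ifelse(use, (al2r / sdy_env)^2, 0)
      v_hat <- ifelse(use, (pk$ct - p$alpha1[pk$rp]) / al2r, 0)
      prec_post <- drop(rowsum(w_prec, rs)) + 1 / p$sigma2
      m_post <- (drop(rowsum(w_prec * v_hat, rs)) + mv / p$sigma2) /
        prec_post
      s_post <- 1 / sqrt(prec_post)
      vp <- stats::rnorm(S, m_post, s_post)
      logw_p <- logw_a; logw_p[env] <- vp[rs]
      # reverse-move proposal parameters evaluated at the proposed state
      sdy_env_p <- .ct_sd0(logw_p[env], p$a1, p$a2, vt, p$sigma2_P)
      w_prec_r <- ifelse(use, (al2r / sdy_env_p)^2, 0)
      prec_post_r <- drop(rowsum(w_prec_r, rs)) + 1 / p$sigma2
      m_post_r <- (drop(rowsum(w_prec_r * v_hat, rs)) + mv / p$sigma2) /
        prec_post_r
      s_post_r <- 1 / sqrt(prec_post_r)
      rl_cur <- rl_all(logw_a, gam, p$a1, p$a2, p$sigma2_P,
                       p$alpha1, p$alpha2)
      rl_prop <- rl_all(logw_p, gam, p$a1, p$a2, p$sigma2_P,
                        p$alpha1, p$alpha2)
      d_rep <- drop(rowsum(rl_prop[env] - rl_cur[env], rs))
      sdv <- sqrt(p$sigma2)
      d <- d_rep + .ldnorm(vp, mv, sdv) - .ldnorm(v, mv, sdv) +
        .ldnorm(v, m_post_r, s_post_r) - .ldnorm(vp, m_post, s_post)
      ok <- is.finite(d) & log(stats::runif(S)) < d
      v[ok] <- vp[ok]
      logw_a[env] <- v[rs]
      acc$v <- acc$v + ok
    }

    ## --- site availability l: exact Gibbs (fully conjugate given v, the ---
    ## AR neighbours and the regression), drawn in time-parity blocks so the
    ## conditioned neighbours stay fixed within a sweep
    if (do_block("l")) {
      vres <- drop(rowsum(v - xwb, so))        # sum over samples per occasion
      vres_full <- numeric(nT); vres_full[sort(unique(so))] <- vres
      M_occ <- tabulate(so, nT)
      rho_occ <- p$rho[pk$site_of_occ]
      for (parity in 0:1) {
        B <- which(pk$time_of_occ %% 2L == parity)
        tB <- pk$time_of_occ[B]
        prev_idx <- B - n; next_idx <- B + n
        # own prior term
        own_prec <- ifelse(tB == 1L, 1 / p$tau2_1, 1 / p$tau2)
        own_mean <- ifelse(tB == 1L,
                           p$beta_b0 + as.vector(eta)[B],
                           rho_occ[B] * (lf[pmax(prev_idx, 1L)] -
                                           as.vector(eta)[pmax(prev_idx, 1L)]) +
                             as.vector(eta)[B])
        prec <- own_prec + M_occ[B] / p$sigma2
        b <- own_prec * own_mean + vres_full[B] / p$sigma2
        # successor term: l_{t+1} ~ N(rho (l_t - eta_t) + eta_{t+1}, tau2)
        has_next <- tB < T
        if (any(has_next)) {
          nb <- next_idx[has_next]
          rh <- rho_occ[B][has_next]
          cc <- lf[nb] - as.vector(eta)[nb] + rh * as.vector(eta)[B][has_next]
          prec[has_next] <- prec[has_next] + rh^2 / p$tau2
          b[has_next] <- b[has_next] + rh * cc / p$tau2
        }
        lf[B] <- stats::rnorm(length(B), b / prec, 1 / sqrt(prec))
      }
      mv <- lf[so] + xwb
      l <- matrix(lf, n, T)
      acc$l <- acc$l + 1
    }

    ## --- availability regression and AR hierarchy ------------------------
    if (do_block("beta_b")) {
      # conjugate joint draw of (beta_b0, beta_b) given l, rho and variances:
      # the availability stage is linear-Gaussian in the coefficients
      q <- qb + 1L
      Xr <- matrix(0, nT, q)
      yv <- numeric(nT)
      st1 <- sqrt(p$tau2_1); st <- sqrt(p$tau2)
      Xr[seq_len(n), 1L] <- 1 / st1
      if (qb) Xr[seq_len(n), -1L] <- pk$Xb[seq_len(n), , drop = FALSE] / st1
      yv[seq_len(n)] <- lf[seq_len(n)] / st1
      if (T > 1L) {
        idx <- (n + 1L):nT
        rho_row <- p$rho[pk$site_of_occ[idx]]
        if (qb) Xr[idx, -1L] <- (pk$Xb[idx, , drop = FALSE] -
                                   rho_row * pk$Xb[idx - n, , drop = FALSE]) / st
        yv[idx] <- (lf[idx] - rho_row * lf[idx - n]) / st
      }
      m0 <- c(priors$beta_b0$mean, rep(priors$beta_b$mean, qb))
      prec0 <- diag(c(1 / priors$beta_b0$sd^2,
                      rep(1 / priors$beta_b$sd^2, qb)), q)
      A <- crossprod(Xr) + prec0
      b <- crossprod(Xr, yv) + prec0 %*% m0
      ch <- chol(A)
      mean_b <- backsolve(ch, backsolve(ch, b, transpose = TRUE))
      draw <- mean_b + backsolve(ch, stats::rnorm(q))
      p$beta_b0 <- draw[1L]
      if (qb) p$beta_b <- draw[-1L]
      eta <- .eta_matrix(pk$Xb, p$beta_b, n, T)
    }

    if (do_block("rho") && T > 1L) {
      # conjugate per-site draw of the AR rate given the detrended process
      prev <- l[, -T, drop = FALSE] - eta[, -T, drop = FALSE]
      resp <- l[, -1L, drop = FALSE] - eta[, -1L, drop = FALSE]
      prec <- rowSums(prev^2) / p$tau2 + 1 / p$sigma2_rho
      mean_r <- (rowSums(prev * resp) / p$tau2 + p$rho0 / p$sigma2_rho) / prec
      p$rho <- stats::rnorm(n, mean_r, 1 / sqrt(prec))
      # conjugate hierarchy mean
      prec0 <- n / p$sigma2_rho + 1 / priors$rho0$sd^2
      mean0 <- (sum(p$rho) / p$sigma2_rho +
                  priors$rho0$mean / priors$rho0$sd^2) / prec0
      p$rho0 <- stats::rnorm(1L, mean0, 1 / sqrt(prec0))
      sr <- sqrt(p$sigma2_rho)
      lsr <- scalar_mh("lsig_rho", log(sr), function(x)
        sum(.ldnorm(p$rho, p$rho0, exp(x))) -
          sum(.ldnorm(p$rho, p$rho0, sr)) +
          .lhalfnorm(exp(x), priors$sd$scale) - .lhalfnorm(sr, priors$sd$scale) +
          x - log(sr))  # Jacobian of the log-sd transform
      p$sigma2_rho <- exp(lsr)^2
    }

    if (do_block("var_avail")) {
      at <- function(tau2, tau2_1) sum(avail_terms(l, p$beta_b0, eta, p$rho,
                                                   tau2, tau2_1))
      if (T > 1L) {
        st <- sqrt(p$tau2)
        lt <- scalar_mh("ltau", log(st), function(x)
          at(exp(2 * x), p$tau2_1) - at(p$tau2, p$tau2_1) +
            .lhalfnorm(exp(x), priors$sd$scale) -
            .lhalfnorm(st, priors$sd$scale) + x - log(st))
        p$tau2 <- exp(2 * lt)
      }
      st1 <- sqrt(p$tau2_1)
      lt1 <- scalar_mh("ltau1", log(st1), function(x)
        at(p$tau2, exp(2 * x)) - at(p$tau2, p$tau2_1) +
          .lhalfnorm(exp(x), priors$sd$scale) -
          .lhalfnorm(st1, priors$sd$scale) + x - log(st1))
      p$tau2_1 <- exp(2 * lt1)
    }

    if (do_block("sigma2")) {
      ss <- sqrt(p$sigma2)
      lss <- scalar_mh("lsig", log(ss), function(x)
        sum(.ldnorm(v, mv, exp(x))) - sum(.ldnorm(v, mv, ss)) +
          .lhalfnorm(exp(x), priors$sd$scale) -
          .lhalfnorm(ss, priors$sd$scale) + x - log(ss))
      p$sigma2 <- exp(2 * lss)
    }

    ## --- collection regression -------------------------------------------
    if (do_block("beta_w") && qw > 0L) {
      # conjugate joint draw given v and l: v - l is linear-Gaussian in beta_w
      resid <- v - lf[so]
      prec0 <- diag(rep(1 / priors$beta_w$sd^2, qw), qw)
      A <- crossprod(pk$Xw) / p$sigma2 + prec0
      b <- crossprod(pk$Xw, resid) / p$sigma2 +
        prec0 %*% rep(priors$beta_w$mean, qw)
      ch <- chol(A)
      mean_b <- backsolve(ch, backsolve(ch, b, transpose = TRUE))
      p$beta_w <- drop(mean_b + backsolve(ch, stats::rnorm(qw)))
      xwb <- drop(pk$Xw %*% p$beta_w)
      mv <- lf[so] + xwb
    }

    ## --- plate standard-curve coefficients -------------------------------
    if (do_block("alpha")) {
      sa <- sqrt(p$sigma2_alpha)
      rl_cur <- rl_all(logw_a, gam, p$a1, p$a2, p$sigma2_P,
                       p$alpha1, p$alpha2)
      for (which_a in 1:2) {
        cur <- if (which_a == 1L) p$alpha1 else p$alpha2
        mu0 <- if (which_a == 1L) p$alpha1_0 else p$alpha2_0
        stp <- if (which_a == 1L) exp(ls$alpha1) else exp(ls$alpha2)
        prop <- cur + stp * stats::rnorm(P)
        a1v <- if (which_a == 1L) prop else p$alpha1
        a2v <- if (which_a == 1L) p$alpha2 else prop
        rl_prop <- rl_all(logw_a, gam, p$a1, p$a2, p$sigma2_P, a1v, a2v)
        dx <- rl_prop - rl_cur
        d_by <- numeric(P)
        tmp <- rowsum(dx, plate_a)
        d_by[as.integer(rownames(tmp))] <- drop(tmp)
        d <- d_by + .ldnorm(prop, mu0, sa) - .ldnorm(cur, mu0, sa)
        ok <- is.finite(d) & log(stats::runif(P)) < d
        if (which_a == 1L) {
          p$alpha1[ok] <- prop[ok]; acc$alpha1 <- acc$alpha1 + ok
        } else {
          p$alpha2[ok] <- prop[ok]; acc$alpha2 <- acc$alpha2 + ok
        }
        if (any(ok)) {
          sel <- ok[plate_a]          # rows on accepted plates
          rl_cur[sel] <- rl_prop[sel]
        }
      }
    }

    if (do_block("alpha_hier")) {
      sa <- sqrt(p$sigma2_alpha)
      # conjugate draws of the hierarchy means
      cj <- function(vals, prior) {
        prec <- P / p$sigma2_alpha + 1 / prior$sd^2
        m <- (sum(vals) / p$sigma2_alpha + prior$mean / prior$sd^2) / prec
        stats::rnorm(1L, m, 1 / sqrt(prec))
      }
      p$alpha1_0 <- cj(p$alpha1, priors$alpha1_0)
      p$alpha2_0 <- cj(p$alpha2, priors$alpha2_0)
      hier <- function(s) sum(.ldnorm(p$alpha1, p$alpha1_0, s)) +
        sum(.ldnorm(p$alpha2, p$alpha2_0, s))
      lsa <- scalar_mh("lsig_alpha", log(sa), function(x)
        hier(exp(x)) - hier(sa) +
          .lhalfnorm(exp(x), priors$sd$scale) -
          .lhalfnorm(sa, priors$sd$scale) + x - log(sa))
      p$sigma2_alpha <- exp(2 * lsa)
    }

    ## --- CT variance model -----------------------------------------------
    if (do_block("ct_var")) {
      i0 <- which(gam == 0L)
      mu0v <- p$alpha1[plate_a[i0]] + p$alpha2[plate_a[i0]] * logw_a[i0]
      ll0 <- function(a1, a2, s2P) sum(.comp_ll(
        ct_a[i0], mu0v, .ct_sd0(logw_a[i0], a1, a2, vt, s2P),
        0L, sigma_c, ct_max))
      if (vt == "const_var") {
        sp_ <- sqrt(p$sigma2_P)
        lsp <- scalar_mh("lsigP", log(sp_), function(x)
          ll0(p$a1, p$a2, exp(2 * x)) - ll0(p$a1, p$a2, p$sigma2_P) +
            .lhalfnorm(exp(x), priors$sd$scale) -
            .lhalfnorm(sp_, priors$sd$scale) + x - log(sp_))
        p$sigma2_P <- exp(2 * lsp)
      } else {
        cur0 <- ll0(p$a1, p$a2, p$sigma2_P)
        a1_old <- p$a1
        p$a1 <- scalar_mh("a1", p$a1, function(x)
          ll0(x, p$a2, p$sigma2_P) - cur0 +
            .ldnorm(x, priors$a1$mean, priors$a1$sd) -
            .ldnorm(p$a1, priors$a1$mean, priors$a1$sd))
        if (p$a1 != a1_old) cur0 <- ll0(p$a1, p$a2, p$sigma2_P)
        p$a2 <- scalar_mh("a2", p$a2, function(x)
          ll0(p$a1, x, p$sigma2_P) - cur0 +
            .ldnorm(x, priors$a2$mean, priors$a2$sd) -
            .ldnorm(p$a2, priors$a2$mean, priors$a2$sd))
      }
    }

    ## --- adaptation (burn-in only) ----------------------------------------
    if (adapting && iter %% control$adapt_interval == 0L) {
      n_batch <- n_batch + 1L
      gain <- 1 / sqrt(n_batch)
      upd <- function(lsv, accv)
        lsv + gain * (accv / control$adapt_interval - 0.44)
      ls$v <- upd(ls$v, acc$v); ls$l <- upd(ls$l, acc$l)
      ls$rho <- upd(ls$rho, acc$rho)
      ls$alpha1 <- upd(ls$alpha1, acc$alpha1)
      ls$alpha2 <- upd(ls$alpha2, acc$alpha2)
      ls$scalars <- upd(ls$scalars, acc$scalars)
      for (nm in names(acc)) acc_total[[nm]] <- acc_total[[nm]] + acc[[nm]]
      acc <- lapply(acc, function(x) x * 0)
      names(acc$scalars) <- names(ls$scalars)
    }

    ## --- retain -----------------------------------------------------------
    if (iter > control$n_burnin &&
        (iter - control$n_burnin) %% control$thin == 0L && kk < n_keep) {
      kk <- kk + 1L
      pv <- c(beta_b0 = p$beta_b0,
              if (qb) stats::setNames(p$beta_b, paste0("beta_b", seq_len(qb))),
              if (qw) stats::setNames(p$beta_w, paste0("beta_w", seq_len(qw))),
              stats::setNames(p$rho, paste0("rho[", seq_len(n), "]")),
              rho0 = p$rho0, sigma2_rho = p$sigma2_rho, tau2 = p$tau2,
              tau2_1 = p$tau2_1, sigma2 = p$sigma2,
              alpha1_0 = p$alpha1_0, alpha2_0 = p$alpha2_0,
              sigma2_alpha = p$sigma2_alpha, a1 = p$a1, a2 = p$a2,
              sigma2_P = p$sigma2_P, p_c = p$p_c, p_h = p$p_h,
              stats::setNames(p$alpha1, paste0("alpha1[", seq_len(P), "]")),
              stats::setNames(p$alpha2, paste0("alpha2[", seq_len(P), "]")))
      if (is.null(keep_params))
        keep_params <- matrix(NA_real_, n_keep, length(pv),
                              dimnames = list(NULL, names(pv)))
      keep_params[kk, ] <- pv
      keep_l[kk, ] <- lf
      keep_v[kk, ] <- v
      gamma_prob[cbind(seq_len(nA), gam + 1L)] <-
        gamma_prob[cbind(seq_len(nA), gam + 1L)] + 1
      if (control$save_gamma) keep_gamma[kk, ] <- gam
    }
    if (control$verbose && iter %% 1000L == 0L)
      message(sprintf("chain %d iter %d / %d", chain_id, iter,
                      control$n_iter))
  }

  colnames(keep_l) <- paste0("l[", rep(seq_len(n), T), ",",
                             rep(seq_len(T), each = n), "]")
  for (nm in names(acc)) acc_total[[nm]] <- acc_total[[nm]] + acc[[nm]]
  total_rate <- lapply(acc_total, function(x) x / control$n_iter)
  list(params = keep_params, l = keep_l, v = keep_v,
       gamma = keep_gamma, gamma_prob = gamma_prob / max(kk, 1L),
       accept = total_rate)
}

#' Split-R-hat and effective sample size of posterior draws
#'
#' Rank-free split-R-hat (each chain split in half) and a
#' pairwise-autocorrelation effective sample size, computed per scalar
#' column.
#'
#' @param draws matrix of draws (rows = iterations).
#' @param chain integer chain index per row (defaults to a single chain).
#' @return data.frame with `param`, `rhat`, `ess`.
#' @export
convergence_summary <- function(draws, chain = NULL) {
  draws <- as.matrix(draws)
  if (is.null(chain)) chain <- rep(1L, nrow(draws))
  out <- data.frame(param = colnames(draws) %||%
                      paste0("V", seq_len(ncol(draws))),
                    rhat = NA_real_, ess = NA_real_)
  split_chains <- function(x, ch) {
    res <- list()
    for (c0 in unique(ch)) {
      xi <- x[ch == c0]
      h <- length(xi) %/% 2L
      if (h >= 2L) res <- c(res, list(xi[1:h], xi[(h + 1):(2 * h)]))
    }
    res
  }
  for (j in seq_len(ncol(draws))) {
    sc <- split_chains(draws[, j], chain)
    m <- length(sc); nn <- length(sc[[1L]])
    if (m >= 2L && nn >= 2L) {
      mu <- vapply(sc, mean, 0); s2 <- vapply(sc, stats::var, 0)
      W <- mean(s2); B <- nn * stats::var(mu)
      out$rhat[j] <- if (W > 1e-12) sqrt(((nn - 1) / nn * W + B / nn) / W)
      else 1
    } else out$rhat[j] <- 1
    x <- draws[, j]
    if (stats::var(x) > 1e-12) {
      ac <- stats::acf(x, lag.max = min(200L, length(x) - 2L),
                       plot = FALSE)$acf[-1L]
      # initial positive sequence estimator on paired sums
      ssum <- 0
      for (k in seq(1L, length(ac) - 1L, by = 2L)) {
        pair <- ac[k] + ac[k + 1L]
        if (is.na(pair) || pair < 0) break
        ssum <- ssum + pair
      }
      out$ess[j] <- length(x) / (1 + 2 * ssum)
    } else out$ess[j] <- length(x)
  }
  out
}

#' Posterior summaries of an eDNA model fit
#'
#' Means, sds, equal-tailed 95% intervals (2.5% and 97.5% quantiles, R type-7
#' interpolation), split-R-hat and effective sample size per scalar
#' parameter.
#'
#' @param fit an `edna_fit`.
#' @param what `"params"`, `"l"` or `"both"`.
#' @param level credible level (default 0.95).
#' @return data.frame of summaries.
#' @export
posterior_summary <- function(fit, what = c("params", "l", "both"),
                              level = 0.95) {
  what <- match.arg(what)
  m <- switch(what, params = fit$params, l = fit$l,
              both = cbind(fit$params, fit$l))
  a <- (1 - level) / 2
  qs <- t(apply(m, 2L, stats::quantile, probs = c(a, 1 - a), names = FALSE))
  cs <- convergence_summary(m, fit$chain)
  data.frame(param = colnames(m), mean = colMeans(m),
             sd = apply(m, 2L, stats::sd), lower = qs[, 1L],
             upper = qs[, 2L], rhat = cs$rhat, ess = cs$ess,
             row.names = NULL)
}

#' Posterior predictive CT distribution over a concentration grid
#'
#' For each DNA amount in `w_grid` and the given plate, averages over
#' retained draws the mixture's exact censoring probability, the mean of the
#' uncensored CT law, and equal-tailed predictive interval endpoints
#' (computed from the mixture CDF on a cycle grid).
#'
#' @param fit an `edna_fit`.
#' @param w_grid positive DNA amounts.
#' @param plate plate index.
#' @param level interval level.
#' @param max_draws subsample of draws used (for speed).
#' @return data.frame with `w`, `mean_ct`, `lower`, `upper`,
#'   `p_censored`.
#' @export
posterior_predict_ct <- function(fit, w_grid, plate = 1L, level = 0.95,
                                 max_draws = 200L) {
  if (!length(w_grid)) stop("w_grid must be non-empty")
  if (any(w_grid <= 0)) stop("w_grid must be positive")
  dr <- fit$params
  idx <- if (nrow(dr) > max_draws)
    round(seq(1L, nrow(dr), length.out = max_draws)) else seq_len(nrow(dr))
  ct_max <- fit$init$params$ct_max
  sigma_c <- fit$init$params$sigma_c
  vt <- fit$variant$tag
  grid_ct <- seq(0, ct_max, length.out = 2001L)
  a <- (1 - level) / 2
  out <- lapply(w_grid, function(w) {
    lw <- log(w)
    cdf_acc <- numeric(length(grid_ct)); pc_acc <- 0; mean_acc <- 0
    for (i in idx) {
      al1 <- dr[i, paste0("alpha1[", plate, "]")]
      al2 <- dr[i, paste0("alpha2[", plate, "]")]
      mu <- al1 + al2 * lw
      sdy <- if (vt == "const_var") sqrt(dr[i, "sigma2_P"])
      else exp((dr[i, "a1"] + dr[i, "a2"] * lw) / 2)
      pc <- dr[i, "p_c"]; ph <- dr[i, "p_h"]
      wts <- c(1 - pc - ph, pc, ph)
      # component CDFs of the uncensored law on the cycle grid
      F0 <- stats::pnorm(grid_ct, mu, sdy)
      Z1 <- max(0.5 - stats::pnorm(0, mu, sigma_c), 1e-300)
      F1 <- if (mu > 0)
        pmin(pmax(stats::pnorm(pmin(grid_ct, mu), mu, sigma_c) -
                    stats::pnorm(0, mu, sigma_c), 0) / Z1, 1)
      else rep(0, length(grid_ct))
      F2 <- pmax(stats::pnorm(pmax(grid_ct, mu), mu, sigma_c) - 0.5, 0) / 0.5
      Fmix <- wts[1L] * F0 + wts[2L] * F1 + wts[3L] * F2
      cdf_acc <- cdf_acc + Fmix
      pc_acc <- pc_acc + (1 - Fmix[length(grid_ct)])
      # mean of the uncensored mixture law (truncated-normal moments)
      e1 <- if (mu > 0) {
        a_ <- (0 - mu) / sigma_c; b_ <- 0
        mu + sigma_c * (stats::dnorm(a_) - stats::dnorm(b_)) /
          (stats::pnorm(b_) - stats::pnorm(a_))
      } else mu
      e2 <- mu + sigma_c * stats::dnorm(0) / 0.5
      mean_acc <- mean_acc + wts[1L] * mu + wts[2L] * e1 + wts[3L] * e2
    }
    cdf <- cdf_acc / length(idx)
    qf <- function(q) {
      if (q <= cdf[1L]) return(grid_ct[1L])
      k <- findInterval(q, cdf)
      if (k >= length(grid_ct)) return(grid_ct[length(grid_ct)])
      x0 <- grid_ct[k]; x1 <- grid_ct[k + 1L]
      c0 <- cdf[k]; c1 <- cdf[k + 1L]
      if (c1 - c0 < 1e-12) x0 else x0 + (q - c0) / (c1 - c0) * (x1 - x0)
    }
    data.frame(w = w, mean_ct = mean_acc / length(idx),
               lower = qf(a), upper = qf(1 - a),
               p_censored = pc_acc / length(idx))
  })
  do.call(rbind, out)
}
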