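#' Mean squared error of posterior mean log-availability
#'
#' `MSE = (1 / (N n T)) * sum_j sum_i sum_t (l[i,t,j] - lhat[i,t,j])^2`
#' across `N` simulated datasets.
#'
#' @param true_l list (length `N`) of true `n x T` matrices, or a single
#'   matrix.
#' @param est_l matching list (or matrix) of posterior means.
#' @return Scalar MSE.
#' @export
mse_l <- function(true_l, est_l) {
  if (is.matrix(true_l)) true_l <- list(true_l)
  if (is.matrix(est_l)) est_l <- list(est_l)
  if (length(true_l) != length(est_l)) stop("mismatched dataset counts")
  tot <- 0; cells <- 0
  for (j in seq_along(true_l)) {
    a <- as.matrix(true_l[[j]]); b <- as.matrix(est_l[[j]])
    if (!all(dim(a) == dim(b))) stop("shape mismatch in dataset ", j)
    tot <- tot + sum((a - b)^2)
    cells <- cells + length(a)
  }
  tot / cells
}

#' Mean bias of posterior means across simulated datasets
#'
#' `MB = (1 / N) * sum_j (theta_hat_j - theta_j)`.
#'
#' @param true_theta true values, one per dataset.
#' @param est_theta posterior means, one per dataset.
#' @return Scalar mean bias.
#' @export
mean_bias <- function(true_theta, est_theta) {
  if (!length(true_theta)) stop("empty input")
  if (length(true_theta) != length(est_theta)) stop("length mismatch")
  mean(est_theta - true_theta)
}

#' Equal-tailed credible interval metrics
#'
#' Per scalar: the `(1-level)/2` and `1-(1-level)/2` posterior quantiles
#' (R's type-7 linear interpolation between order statistics). Returns the
#' mean interval width, the fraction of scalars whose truth is covered, and
#' the fraction of intervals containing zero.
#'
#' @param draws matrix of posterior draws (rows = iterations, columns =
#'   scalars) or a vector for a single scalar.
#' @param truth true value per column.
#' @param level credible level in (0, 1), default 0.95.
#' @return List with `width` (mean interval range), `coverage`,
#'   `contains_zero`, and the per-scalar `lower`/`upper` bounds.
#' @export
interval_metrics <- function(draws, truth, level = 0.95) {
  if (level <= 0 || level >= 1) stop("level must be in (0, 1)")
  draws <- as.matrix(draws)
  if (!nrow(draws)) stop("draws must be non-empty")
  if (length(truth) != ncol(draws)) stop("truth length mismatch")
  a <- (1 - level) / 2
  lo <- apply(draws, 2L, stats::quantile, probs = a, names = FALSE)
  hi <- apply(draws, 2L, stats::quantile, probs = 1 - a, names = FALSE)
  list(width = mean(hi - lo),
       coverage = mean(truth >= lo & truth <= hi),
       contains_zero = mean(lo <= 0 & 0 <= hi),
       lower = lo, upper = hi)
}

# Reproducible per-cell seed: mixes the base seed with the cell's design so
# every cell is independently re-runnable and all model variants inside a
# cell see the same simulated datasets (paired comparison).
.cell_seed <- function(seed, M, K, p_c, p_h) {
  .sub_seed(seed, M, K, round(1e5 * p_c), round(1e5 * p_h))
}

#' Run a scaled simulation study over survey designs
#'
#' For each cell of the design grid (samples-per-occasion `M`, replicates
#' `K`, contamination/inhibition setting), simulates `N` surveys and fits
#' each requested model variant to the *same* `N` datasets, then summarises
#' the log-availability posterior (MSE, mean 95% interval width `R`,
#' coverage `C`) and the per-parameter mean bias, interval width and
#' contains-zero proportion.
#'
#' @param grid data.frame with columns `M`, `K`, `p_c`, `p_h` (one row per
#'   cell).
#' @param variants character vector of model variants fitted to every cell.
#' @param N simulated datasets per cell.
#' @param n_sites,n_times survey dimensions.
#' @param control an [mcmc_control()]; use a scaled preset — full
#'   reference-scale studies (N = 100 per cell, 16 designs) are
#'   cluster-scale.
#' @param seed base seed; cells are seeded independently via a deterministic
#'   mix of the seed and the cell design.
#' @param sim_args named list of overrides passed to [sim_config()] (e.g.
#'   `params`).
#' @param rhat_threshold fits with any availability-block split-R-hat above
#'   this are flagged in the output (not dropped).
#' @return List with `cells` (one row per cell x variant: `p_c`, `p_h`, `M`,
#'   `K`, `model`, `MSE`, `R`, `C`, `n_flagged`) and `params` (long table of
#'   per-parameter MB / width / contains-zero).
#' @export
run_sim_study <- function(grid, variants = c("full", "const_var",
                                             "no_mixture"),
                          N = 2, n_sites = 10, n_times = 20,
                          control = mcmc_control(preset = "test"),
                          seed = 1L, sim_args = list(),
                          rhat_threshold = 1.1) {
  cells <- list(); par_rows <- list()
  track <- c("beta_b1", "beta_b2", "beta_w1", "beta_w2", "a1", "a2",
             "p_c", "p_h")
  for (r in seq_len(nrow(grid))) {
    M <- grid$M[r]; K <- grid$K[r]
    p_c <- grid$p_c[r]; p_h <- grid$p_h[r]
    cseed <- .cell_seed(seed, M, K, p_c, p_h)
    design <- survey_design(n_sites, n_times, M, K)
    res <- list()
    for (j in seq_len(N)) {
      cfg_args <- c(list(design = design, seed = .sub_seed(cseed, j)),
                    sim_args)
      if (is.null(cfg_args$params)) {
        cfg_args$params <- model_parameters(
          beta_b0 = 6, beta_b = c(1, -1), beta_w = c(1, -1), rho = 1,
          rho0 = 1, tau2 = 1, tau2_1 = 1, sigma2 = 1, a1 = 0.2, a2 = -0.25,
          p_c = p_c, p_h = p_h, sigma_c = 40, ct_max = 40)
      }
      sim <- simulate_survey(do.call(sim_config, cfg_args))
      for (vt in variants) {
        ctl <- control
        ctl$seed <- .sub_seed(cseed, j, match(vt, variants))
        fit <- fit_edna(sim$dataset, variant = vt, control = ctl)
        lm_mean <- matrix(colMeans(fit$l), n_sites, n_times)
        im <- interval_metrics(fit$l, as.vector(sim$latent$l))
        cs <- convergence_summary(fit$l[, seq_len(min(20L, ncol(fit$l))),
                                        drop = FALSE], fit$chain)
        flagged <- any(cs$rhat > rhat_threshold, na.rm = TRUE)
        pm <- colMeans(fit$params)
        truth_par <- c(beta_b1 = sim$params$beta_b[1],
                       beta_b2 = sim$params$beta_b[2],
                       beta_w1 = sim$params$beta_w[1],
                       beta_w2 = sim$params$beta_w[2],
                       a1 = sim$params$a1, a2 = sim$params$a2,
                       p_c = sim$params$p_c, p_h = sim$params$p_h)
        have <- intersect(track, colnames(fit$params))
        imp <- interval_metrics(fit$params[, have, drop = FALSE],
                                truth_par[have])
        res[[length(res) + 1L]] <- list(
          j = j, model = vt, true_l = sim$latent$l, est_l = lm_mean,
          width = im$width, coverage = im$coverage, flagged = flagged,
          par = data.frame(M = M, K = K, p_c = p_c, p_h = p_h, model = vt,
                           j = j, param = have,
                           truth = as.numeric(truth_par[have]),
                           est = as.numeric(pm[have]),
                           lower = imp$lower, upper = imp$upper))
      }
    }
    for (vt in variants) {
      sub <- Filter(function(x) x$model == vt, res)
      cells[[length(cells) + 1L]] <- data.frame(
        p_c = p_c, p_h = p_h, M = M, K = K, model = vt,
        MSE = mse_l(lapply(sub, `[[`, "true_l"),
                    lapply(sub, `[[`, "est_l")),
        R = mean(vapply(sub, `[[`, 0, "width")),
        C = mean(vapply(sub, `[[`, 0, "coverage")),
        N = length(sub),
        n_flagged = sum(vapply(sub, `[[`, TRUE, "flagged")))
      par_rows[[length(par_rows) + 1L]] <-
        do.call(rbind, lapply(sub, `[[`, "par"))
    }
  }
  par_long <- do.call(rbind, par_rows)
  par_sum <- do.call(rbind, lapply(
    split(par_long, list(par_long$M, par_long$K, par_long$p_c,
                         par_long$p_h, par_long$model, par_long$param),
          drop = TRUE),
    function(g) data.frame(
      M = g$M[1], K = g$K[1], p_c = g$p_c[1], p_h = g$p_h[1],
      model = g$model[1], param = g$param[1],
      MB = mean_bias(g$truth, g$est), width = mean(g$upper - g$lower),
      contains_zero = mean(g$lower <= 0 & 0 <= g$upper))))
  rownames(par_sum) <- NULL
  list(cells = do.call(rbind, cells), params = par_sum, draws_long = par_long)
}

#' Per-plate standard-curve regression diagnostic
#'
#' Fits ordinary least squares of CT on log-concentration separately per
#' plate (censored standards excluded and counted), returning the fitted
#' coefficients and the residuals keyed by concentration — the classic
#' standard-curve picture: near-parallel plate lines with negative slope,
#' residual spread growing as the concentration shrinks.
#'
#' @param standards data.frame with `plate`, `concentration`, `ct`
#'   (`NA` = censored).
#' @return List with `fits` (data.frame `plate`, `intercept`, `slope`,
#'   `n_used`, `n_censored`) and `residuals` (data.frame `plate`,
#'   `concentration`, `residual`).
#' @export
standards_regression_diagnostic <- function(standards) {
  std <- as.data.frame(standards)
  fits <- list(); resids <- list()
  for (p in sort(unique(std$plate))) {
    sub <- std[std$plate == p, ]
    ok <- !is.na(sub$ct)
    n_cens <- sum(!ok)
    sub <- sub[ok, ]
    if (length(unique(sub$concentration)) < 2L)
      stop("plate ", p, " has fewer than 2 distinct uncensored concentrations")
    f <- stats::lm(ct ~ log(concentration), data = sub)
    fits[[length(fits) + 1L]] <- data.frame(
      plate = p, intercept = stats::coef(f)[1L], slope = stats::coef(f)[2L],
      n_used = nrow(sub), n_censored = n_cens)
    resids[[length(resids) + 1L]] <- data.frame(
      plate = p, concentration = sub$concentration,
      residual = stats::resid(f))
  }
  out <- list(fits = do.call(rbind, fits),
              residuals = do.call(rbind, resids))
  rownames(out$fits) <- rownames(out$residuals) <- NULL
  out
}
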