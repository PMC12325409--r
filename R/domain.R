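#' Describe the layout of a qPCR eDNA survey
#'
#' A survey design records how many sites were surveyed, how many sampling
#' occasions (time points) each site has, how many environmental samples were
#' collected per occasion, how many PCR replicates each sample was split into,
#' which plate each occasion's replicates were analysed on, and the maximum
#' cycle number `ct_max` after which a replicate is recorded as censored
#' (non-amplification).
#'
#' @param n_sites number of sites `n`.
#' @param n_times number of sampling occasions `T` per site.
#' @param samples_per_occasion number of samples `M`; a scalar (same
#'   everywhere) or an `n_sites x n_times` matrix.
#' @param replicates_per_sample number of PCR replicates `K` per sample; a
#'   scalar or an `n_sites x n_times` matrix (applied to every sample of that
#'   occasion).
#' @param plate_of_occasion integer `n_sites x n_times` matrix mapping each
#'   occasion to the plate its replicates were run on. Defaults to one
#'   distinct plate per occasion (the common design where all samples from a
#'   sampling occasion share one PCR run).
#' @param ct_max maximum cycle number (cycles); CT values at or above this are
#'   censored.
#'
#' @return An object of class `edna_design` with elements `n_sites`,
#'   `n_times`, `M`, `plate_map`, `n_plates`, `ct_max` and a `samples`
#'   data.frame (one row per environmental sample: `site`, `time`, `sample`,
#'   `plate`, `K`).
#' @export
survey_design <- function(n_sites, n_times, samples_per_occasion = 1,
                          replicates_per_sample = 1,
                          plate_of_occasion = NULL, ct_max = 40) {
  stopifnot(.is_count(n_sites), .is_count(n_times),
            is.numeric(ct_max), length(ct_max) == 1L, ct_max > 0)
  expand <- function(x, what) {
    if (length(x) == 1L) x <- matrix(x, n_sites, n_times)
    x <- as.matrix(x)
    if (!all(dim(x) == c(n_sites, n_times)))
      stop(sprintf("%s must be scalar or %d x %d", what, n_sites, n_times))
    if (any(x < 1) || any(x != round(x)))
      stop(sprintf("%s must contain positive integers", what))
    storage.mode(x) <- "integer"
    x
  }
  M <- expand(samples_per_occasion, "samples_per_occasion")
  K <- expand(replicates_per_sample, "replicates_per_sample")
  if (is.null(plate_of_occasion)) {
    plate_of_occasion <- matrix(seq_len(n_sites * n_times), n_sites, n_times)
  }
  plate_map <- expand(plate_of_occasion, "plate_of_occasion")

  # Sample table in canonical order: occasion index (t - 1) * n + i, then m.
  occ <- expand.grid(site = seq_len(n_sites), time = seq_len(n_times))
  samples <- do.call(rbind, lapply(seq_len(nrow(occ)), function(r) {
    i <- occ$site[r]; t <- occ$time[r]
    data.frame(site = i, time = t, sample = seq_len(M[i, t]),
               plate = plate_map[i, t], K = K[i, t])
  }))
  rownames(samples) <- NULL
  structure(list(n_sites = as.integer(n_sites), n_times = as.integer(n_times),
                 M = M, plate_map = plate_map,
                 n_plates = max(plate_map), ct_max = as.numeric(ct_max),
                 samples = samples),
            class = "edna_design")
}

#' @export
print.edna_design <- function(x, ...) {
  cat(sprintf(
    "qPCR survey design: %d sites x %d occasions, %d samples, %d replicates, %d plates, CT.max = %g\n",
    x$n_sites, x$n_times, nrow(x$samples), sum(x$samples$K), x$n_plates,
    x$ct_max))
  invisible(x)
}

#' Bundle survey observations into a dataset
#'
#' Collects the design, covariates, per-replicate CT observations and the
#' plate standards into a single object used by the likelihood, inference and
#' evaluation functions. Censored replicates (no amplification by `ct_max`)
#' are encoded as `NA` in the `ct` column; `NA` is a distinct flag, never a
#' numeric sentinel.
#'
#' @param design an [survey_design()] object.
#' @param replicates data.frame with columns `site`, `time`, `sample`,
#'   `replicate`, `plate`, `ct` (`NA` = censored), one row per PCR replicate.
#' @param site_covariates `NULL` or data.frame with columns `site`, `time`
#'   plus one column per site-level covariate (complete cases only).
#' @param sample_covariates `NULL` or data.frame with columns `site`, `time`,
#'   `sample` plus one column per sample-level covariate.
#' @param standards data.frame with columns `plate`, `standard_id`,
#'   `concentration` (known amount, strictly positive, natural units) and
#'   `ct` (`NA` = censored).
#' @param validate if `TRUE` (default) stop when [validate_dataset()] reports
#'   violations.
#'
#' @return An object of class `edna_survey`.
#' @export
survey_dataset <- function(design, replicates, site_covariates = NULL,
                           sample_covariates = NULL, standards,
                           validate = TRUE) {
  stopifnot(inherits(design, "edna_design"))
  replicates <- as.data.frame(replicates)
  standards <- as.data.frame(standards)
  need <- c("site", "time", "sample", "replicate", "plate", "ct")
  if (!all(need %in% names(replicates)))
    stop("replicates must have columns ", paste(need, collapse = ", "))
  need_s <- c("plate", "standard_id", "concentration", "ct")
  if (!all(need_s %in% names(standards)))
    stop("standards must have columns ", paste(need_s, collapse = ", "))
  # canonical ordering: occasion, sample, replicate
  ord <- order((replicates$time - 1L) * design$n_sites + replicates$site,
               replicates$sample, replicates$replicate)
  replicates <- replicates[ord, , drop = FALSE]
  rownames(replicates) <- NULL
  obj <- structure(list(design = design, replicates = replicates,
                        site_covariates = site_covariates,
                        sample_covariates = sample_covariates,
                        standards = standards),
                   class = "edna_survey")
  if (validate) {
    viol <- validate_dataset(obj)
    if (nrow(viol))
      stop("invalid survey dataset:\n",
           paste(utils::head(viol$message, 10L), collapse = "\n"))
  }
  obj
}

#' @export
print.edna_survey <- function(x, ...) {
  print(x$design)
  cat(sprintf("  replicates: %d (%d censored); standards: %d (%d censored)\n",
              nrow(x$replicates), sum(is.na(x$replicates$ct)),
              nrow(x$standards), sum(is.na(x$standards$ct))))
  cat(sprintf("  covariates: %d site-level, %d sample-level\n",
              ncol(.xb_matrix(x)), ncol(.xw_matrix(x))))
  invisible(x)
}

#' Validate a survey dataset against its structural invariants
#'
#' Checks every invariant of the data model: CT values within `(0, ct_max)`
#' when not censored, plate assignments consistent with the design's
#' occasion-to-plate map, exactly one replicate row per design cell, strictly
#' positive standard concentrations, standard plates within range, and
#' complete covariates with consistent dimensions. Violations are reported,
#' not raised.
#'
#' @param dataset an `edna_survey` object.
#' @return A data.frame with columns `check` and `message`, one row per
#'   violation; zero rows means the dataset is valid.
#' @export
validate_dataset <- function(dataset) {
  d <- dataset$design
  rep <- dataset$replicates
  std <- dataset$standards
  out <- list()
  bad <- function(check, message) out[[length(out) + 1L]] <<-
    data.frame(check = check, message = message)

  idx_ok <- rep$site >= 1 & rep$site <= d$n_sites &
    rep$time >= 1 & rep$time <= d$n_times
  for (r in which(!idx_ok))
    bad("index_range", sprintf("replicate row %d: site/time out of range", r))
  obs <- !is.na(rep$ct)
  for (r in which(obs & (rep$ct <= 0 | rep$ct >= d$ct_max)))
    bad("ct_range", sprintf(
      "replicate (i=%d,m=%d,t=%d,k=%d): ct = %g outside (0, %g)",
      rep$site[r], rep$sample[r], rep$time[r], rep$replicate[r],
      rep$ct[r], d$ct_max))
  for (r in which(idx_ok)) {
    p_exp <- d$plate_map[rep$site[r], rep$time[r]]
    if (rep$plate[r] != p_exp)
      bad("plate_consistency", sprintf(
        "replicate (i=%d,m=%d,t=%d,k=%d): plate %d != design plate %d",
        rep$site[r], rep$sample[r], rep$time[r], rep$replicate[r],
        rep$plate[r], p_exp))
  }
  # exactly one replicate row per (i, m, t, k) implied by the design
  key_have <- paste(rep$site, rep$time, rep$sample, rep$replicate)
  key_want <- with(d$samples, unlist(lapply(seq_len(nrow(d$samples)),
    function(r) paste(site[r], time[r], sample[r], seq_len(K[r])))))
  miss <- setdiff(key_want, key_have)
  extra <- setdiff(key_have, key_want)
  dup <- key_have[duplicated(key_have)]
  for (k in miss) bad("cell_missing", paste("missing replicate cell (i t m k):", k))
  for (k in extra) bad("cell_extra", paste("replicate outside design (i t m k):", k))
  for (k in unique(dup)) bad("cell_duplicate", paste("duplicated replicate cell:", k))

  if (nrow(std)) {
    for (r in which(std$concentration <= 0))
      bad("standard_concentration",
          sprintf("standard row %d: concentration %g <= 0", r,
                  std$concentration[r]))
    for (r in which(std$plate < 1 | std$plate > d$n_plates))
      bad("standard_plate", sprintf("standard row %d: plate %d outside 1..%d",
                                    r, std$plate[r], d$n_plates))
    sobs <- !is.na(std$ct)
    for (r in which(sobs & (std$ct <= 0 | std$ct >= d$ct_max)))
      bad("ct_range", sprintf("standard row %d: ct = %g outside (0, %g)",
                              r, std$ct[r], d$ct_max))
  }

  cov_check <- function(df, keys, what, n_expected) {
    if (is.null(df)) return()
    df <- as.data.frame(df)
    if (!all(keys %in% names(df))) {
      bad(paste0(what, "_keys"),
          sprintf("%s must have key columns %s", what,
                  paste(keys, collapse = ", ")))
      return()
    }
    vals <- df[setdiff(names(df), keys)]
    if (anyNA(vals))
      bad(paste0(what, "_missing"), sprintf("%s contain missing values", what))
    if (nrow(df) != n_expected)
      bad(paste0(what, "_rows"), sprintf("%s: %d rows, expected %d", what,
                                         nrow(df), n_expected))
  }
  cov_check(dataset$site_covariates, c("site", "time"), "site_covariates",
            d$n_sites * d$n_times)
  cov_check(dataset$sample_covariates, c("site", "time", "sample"),
            "sample_covariates", nrow(d$samples))

  if (!length(out))
    return(data.frame(check = character(), message = character()))
  do.call(rbind, out)
}

# Site covariate matrix, one row per occasion in canonical order
# occ = (t - 1) * n + i; zero columns when no covariates were recorded.
.xb_matrix <- function(dataset) {
  d <- dataset$design
  nT <- d$n_sites * d$n_times
  sc <- dataset$site_covariates
  if (is.null(sc)) return(matrix(0, nT, 0))
  sc <- as.data.frame(sc)
  ord <- order((sc$time - 1L) * d$n_sites + sc$site)
  sc <- sc[ord, , drop = FALSE]
  as.matrix(sc[setdiff(names(sc), c("site", "time"))])
}

# Sample covariate matrix aligned with design$samples ordering.
.xw_matrix <- function(dataset) {
  d <- dataset$design
  sc <- dataset$sample_covariates
  if (is.null(sc)) return(matrix(0, nrow(d$samples), 0))
  sc <- as.data.frame(sc)
  ord <- order((sc$time - 1L) * d$n_sites + sc$site, sc$sample)
  sc <- sc[ord, , drop = FALSE]
  as.matrix(sc[setdiff(names(sc), c("site", "time", "sample"))])
}

#' Assemble a survey dataset from plain tables
#'
#' Builds an `edna_survey` from the CSV-dialect tables used on disk: a
#' replicate table, optional covariate tables, a standards table, and a
#' design specification (a list with `n_sites`, `n_times`, `ct_max`).
#' Empty or `NA` CT cells are read as censored.
#'
#' @param replicates,site_covariates,sample_covariates,standards data.frames
#'   as documented in [survey_dataset()] (covariates may be `NULL`).
#' @param design_spec list with `n_sites`, `n_times` and `ct_max`; the
#'   occasion-to-plate map and per-cell sample/replicate counts are inferred
#'   from the replicate table.
#' @return A validated `edna_survey` object (an error aggregates the
#'   violations otherwise).
#' @export
assemble_dataset <- function(replicates, site_covariates = NULL,
                             sample_covariates = NULL, standards,
                             design_spec) {
  replicates <- as.data.frame(replicates)
  replicates$ct <- suppressWarnings(as.numeric(replicates$ct))
  n <- design_spec$n_sites
  T <- design_spec$n_times
  M <- matrix(0L, n, T)
  K <- matrix(1L, n, T)
  plate <- matrix(NA_integer_, n, T)
  agg_m <- stats::aggregate(sample ~ site + time, replicates, max)
  agg_k <- stats::aggregate(replicate ~ site + time, replicates, max)
  agg_p <- stats::aggregate(plate ~ site + time, replicates,
                            function(x) x[1L])
  for (r in seq_len(nrow(agg_m)))
    M[agg_m$site[r], agg_m$time[r]] <- agg_m$sample[r]
  for (r in seq_len(nrow(agg_k)))
    K[agg_k$site[r], agg_k$time[r]] <- agg_k$replicate[r]
  for (r in seq_len(nrow(agg_p)))
    plate[agg_p$site[r], agg_p$time[r]] <- agg_p$plate[r]
  if (anyNA(plate)) stop("replicate table does not cover every (site, time)")
  if (any(M < 1)) stop("replicate table has occasions with no samples")
  design <- survey_design(n, T, M, K, plate, ct_max = design_spec$ct_max)
  obj <- survey_dataset(design, replicates, site_covariates,
                        sample_covariates, standards, validate = FALSE)
  viol <- validate_dataset(obj)
  if (nrow(viol))
    stop("assembled dataset failed validation:\n",
         paste(viol$message, collapse = "\n"))
  obj
}

#' Write a survey dataset as CSV tables
#'
#' Writes `replicates.csv`, `site_covariates.csv`, `sample_covariates.csv`,
#' `standards.csv` and `design.json` into `dir`. Censored CT cells are
#' written as empty strings. [read_survey()] inverts this.
#'
#' @param dataset an `edna_survey`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_survey <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(df, f) utils::write.csv(df, file.path(dir, f),
                                         row.names = FALSE, na = "")
  wr(dataset$replicates, "replicates.csv")
  if (!is.null(dataset$site_covariates))
    wr(dataset$site_covariates, "site_covariates.csv")
  if (!is.null(dataset$sample_covariates))
    wr(dataset$sample_covariates, "sample_covariates.csv")
  wr(dataset$standards, "standards.csv")
  d <- dataset$design
  jsonlite::write_json(list(n_sites = d$n_sites, n_times = d$n_times,
                            ct_max = d$ct_max),
                       file.path(dir, "design.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' Read a survey dataset written by [write_survey()]
#'
#' @param dir directory containing the CSV tables and `design.json`.
#' @return An `edna_survey` object.
#' @export
read_survey <- function(dir) {
  rd <- function(f) {
    p <- file.path(dir, f)
    if (!file.exists(p)) return(NULL)
    utils::read.csv(p)
  }
  design_spec <- jsonlite::read_json(file.path(dir, "design.json"),
                                     simplifyVector = TRUE)
  assemble_dataset(rd("replicates.csv"), rd("site_covariates.csv"),
                   rd("sample_covariates.csv"), rd("standards.csv"),
                   design_spec)
}
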