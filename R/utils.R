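# Internal numeric helpers shared across modules.

# Row-wise log-sum-exp of a matrix of log-terms; -Inf rows are handled.
.logsumexp_rows <- function(m) {
  mx <- do.call(pmax, c(lapply(seq_len(ncol(m)), function(j) m[, j]),
                        list(na.rm = FALSE)))
  s <- 0
  for (j in seq_len(ncol(m))) s <- s + exp(m[, j] - mx)
  out <- mx + log(s)
  out[!is.finite(mx)] <- -Inf
  out
}

.logsumexp <- function(x) {
  mx <- max(x)
  if (!is.finite(mx)) return(-Inf)
  mx + log(sum(exp(x - mx)))
}

# log(exp(la) - exp(lb)) for la >= lb, vectorised. Returns -Inf when equal.
.logdiffexp <- function(la, lb) {
  out <- la + log1p(-exp(pmin(lb - la, 0)))
  out[lb >= la] <- -Inf
  out[!is.finite(la)] <- -Inf
  out
}

# Fast vectorised normal log-density (avoids dnorm argument checking in the
# sampler's hot loops).
.ldnorm <- function(x, mean, sd) {
  -0.5 * ((x - mean) / sd)^2 - log(sd) - 0.918938533204672742  # log(sqrt(2*pi))
}

# Derive a bounded positive integer seed from a base seed and offsets; keeps
# the result comfortably inside .Machine$integer.max.
.sub_seed <- function(seed, ...) {
  parts <- c(seed, ...)
  s <- 0
  for (p in parts) s <- (s * 69069 + as.numeric(p) * 7919 + 1) %% 2147480000
  as.integer(s) + 1L
}

.is_count <- function(x) length(x) == 1L && is.numeric(x) && is.finite(x) &&
  x >= 1 && x == round(x)

`%||%` <- function(a, b) if (is.null(a)) b else a
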