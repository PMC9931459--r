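# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state
# afterwards so library code never perturbs the user's random stream.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Derive a sub-stream seed from a base seed; keeps the result a valid
# 32-bit integer whatever the caller passes.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) + offset) %% 2147483000)
}

# Normal truncated below at `lower` via inverse-CDF; `u` in (0,1) may be
# supplied (copula use), otherwise fresh uniforms are drawn.
rnorm_trunc <- function(n, mean, sd, lower, u = NULL) {
  if (is.null(u)) u <- stats::runif(n)
  p0 <- stats::pnorm(lower, mean = mean, sd = sd)
  stats::qnorm(p0 + u * (1 - p0), mean = mean, sd = sd)
}

# md5 of a serialized R object; used to stamp reports with a config hash.
hash_object <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  writeBin(serialize(x, NULL, version = 2), f)
  unname(tools::md5sum(f))
}

# Moore-Penrose pseudo-inverse via SVD; fallback when a log-rank covariance
# submatrix is numerically singular.
pinv <- function(m, tol = sqrt(.Machine$double.eps)) {
  s <- svd(m)
  keep <- s$d > tol * max(s$d, 0)
  if (!any(keep)) return(matrix(0, ncol(m), nrow(m)))
  s$v[, keep, drop = FALSE] %*%
    (t(s$u[, keep, drop = FALSE]) / s$d[keep])
}

stop_validation <- function(...) {
  stop(..., call. = FALSE)
}

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}
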