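# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is untouched. `seed = NULL` uses (and advances) the current stream.
with_local_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    abort("`seed` must be a single finite number or NULL.")
  }
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1L) # initialise the RNG so there is a state to restore
  }
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed %% .Machine$integer.max))
  force(code)
}

# Mix a base seed with small integer tags, staying below 2^31.
derive_seed <- function(seed, ...) {
  tags <- c(...)
  as.integer((seed + sum(tags * 7919^seq_along(tags))) %% 2147483629)
}

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lower || x > upper) {
    abort(sprintf("`%s` must be a single finite number in [%s, %s].",
                  name, format(lower), format(upper)))
  }
  invisible(x)
}

# Minimum eigenvalue check used wherever a correlation matrix enters.
check_correlation_matrix <- function(rho, tol = 1e-8, name = "rho") {
  if (!is.matrix(rho) || nrow(rho) != ncol(rho)) {
    abort(sprintf("`%s` must be a square matrix.", name))
  }
  if (max(abs(rho - t(rho))) > 1e-12) {
    abort(sprintf("`%s` must be symmetric.", name))
  }
  if (max(abs(diag(rho) - 1)) > 1e-12) {
    abort(sprintf("`%s` must have a unit diagonal.", name))
  }
  if (any(rho < -1 - 1e-12) || any(rho > 1 + 1e-12)) {
    abort(sprintf("`%s` entries must lie in [-1, 1].", name))
  }
  ev <- eigen(rho, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -tol) {
    abort(paste0(
      "`", name, "` is not positive semidefinite (minimum eigenvalue ",
      format(min(ev), digits = 6), "); offending matrix:\n",
      paste(utils::capture.output(print(round(rho, 4))), collapse = "\n")
    ))
  }
  invisible(rho)
}

# Symmetric matrix square root that tolerates exact semi-definiteness
# (e.g. sigma = 0), unlike chol().
matrix_sqrt <- function(S) {
  e <- eigen(S, symmetric = TRUE)
  e$vectors %*% (sqrt(pmax(e$values, 0)) * t(e$vectors))
}

required_trial_cols <- c("subject", "task", "stimulus", "response",
                         "accurate", "confidence_level")

assert_trial_table <- function(trials, call_name = "trials") {
  missing <- setdiff(required_trial_cols, names(trials))
  if (length(missing) > 0) {
    abort(sprintf("`%s` is missing required column(s): %s.",
                  call_name, paste(missing, collapse = ", ")))
  }
  invisible(trials)
}
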