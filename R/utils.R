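# Internal helpers: error conditions, seeded evaluation, matrix utilities.

abort_config <- function(msg, call = sys.call(-1)) {
  stop(structure(class = c("skewsort_config_error", "error", "condition"),
                 list(message = msg, call = call)))
}

abort_io <- function(msg, call = sys.call(-1)) {
  stop(structure(class = c("skewsort_io_error", "error", "condition"),
                 list(message = msg, call = call)))
}

abort_degenerate <- function(msg, call = sys.call(-1)) {
  stop(structure(class = c("skewsort_degenerate_error", "error", "condition"),
                 list(message = msg, call = call)))
}

abort_numeric <- function(msg, call = sys.call(-1)) {
  stop(structure(class = c("skewsort_numeric_error", "error", "condition"),
                 list(message = msg, call = call)))
}

#' Evaluate an expression under a temporary RNG seed
#'
#' Runs `code` with the global RNG seeded to `seed`, restoring the previous
#' RNG state afterwards so callers' random streams are not disturbed.
#' With `seed = NULL` the expression is evaluated as-is.
#'
#' @param seed integer seed or `NULL`.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  code
}

# Symmetric eigen-based decompositions of a dispersion matrix, with a ridge
# applied when the condition number exceeds 1e10 (scaled by trace/p).
sigma_decomp <- function(Sigma, reg_eps = 1e-6) {
  p <- nrow(Sigma)
  Sigma <- (Sigma + t(Sigma)) / 2
  e <- eigen(Sigma, symmetric = TRUE)
  if (min(e$values) <= 0 || max(e$values) / max(min(e$values), 1e-300) > 1e10) {
    ridge <- reg_eps * sum(diag(Sigma)) / p
    if (ridge <= 0) ridge <- reg_eps
    Sigma <- Sigma + diag(ridge, p)
    e <- eigen(Sigma, symmetric = TRUE)
    if (min(e$values) <= 0)
      abort_numeric("dispersion matrix is not positive definite after regularization")
  }
  V <- e$vectors
  list(
    Sigma    = Sigma,
    inv      = V %*% (t(V) / e$values),
    inv_sqrt = V %*% (t(V) / sqrt(e$values)),
    sqrt     = V %*% (t(V) * sqrt(e$values)),
    logdet   = sum(log(e$values))
  )
}

# log(sum(exp(x))) along rows of a matrix; column-wise pmax keeps this off
# the profiler's hot list for the narrow matrices the mixtures produce
row_logsumexp <- function(M) {
  if (ncol(M) == 1L) return(as.numeric(M))
  mx <- M[, 1L]
  for (j in 2:ncol(M)) mx <- pmax(mx, M[, j])
  mx + log(rowSums(exp(M - mx)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
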