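# Internal helpers shared across modules.

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

#' Evaluate code under a fixed RNG seed without clobbering the caller's stream
#' @noRd
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stopf("`seed` must be a single non-missing number")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Derive a child seed from a master seed and a named stream
#'
#' Deterministic splitting rule so adding a stage never perturbs another
#' stage's draws: each (master, stream, index) triple maps to a fixed
#' integer in [1, 2^31 - 2] via a Lehmer-style mix.
#'
#' @param master integer master seed.
#' @param stream character stream label (e.g. "simulate", "mc").
#' @param index integer sub-index within the stream (e.g. city number).
#' @return a single integer seed.
#' @export
child_seed <- function(master, stream, index = 0L) {
  m <- 2147483647 # 2^31 - 1, prime
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream))) %% m
  s <- (as.numeric(master) %% m) * 48271 %% m
  s <- (s + h * 69621 + as.numeric(index) * 16807) %% m
  as.integer(if (s == 0) 1 else s)
}

# Symmetrize and check positive semi-definiteness (tolerance on smallest
# eigenvalue relative to the largest).
check_psd <- function(V, tol = 1e-8, label = "vcov") {
  if (max(abs(V - t(V))) > tol * max(1, max(abs(V))))
    stopf("%s is not symmetric within tolerance", label)
  V <- (V + t(V)) / 2
  ev <- eigen(V, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -tol * max(1, max(abs(ev))))
    stopf("%s is not positive semi-definite (min eigenvalue %.3g)",
          label, min(ev))
  V
}

# Draws from N(mu, V) by eigendecomposition (handles PSD V with zero
# eigenvalues, e.g. a degenerate vcov collapsing the draws onto mu).
rmvn <- function(n, mu, V) {
  p <- length(mu)
  V <- check_psd(V)
  ee <- eigen(V, symmetric = TRUE)
  lam <- pmax(ee$values, 0)
  A <- ee$vectors %*% (t(ee$vectors) * sqrt(lam))
  Z <- matrix(stats::rnorm(n * p), n, p)
  sweep(Z %*% t(A), 2, mu, "+")
}

is_count <- function(x) is.numeric(x) && all(is.finite(x)) && all(x >= 0) &&
  all(abs(x - round(x)) < 1e-8)
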