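# Internal numerical helpers shared across modules.

#' Solve a symmetric positive (semi-)definite system with jitter fallback
#'
#' Attempts a Cholesky solve of `M x = b` (or a full inverse when `b` is
#' missing); on failure adds `1e-8 * mean(diag(M))` to the diagonal and retries
#' once before giving up.
#'
#' @param M symmetric matrix.
#' @param b optional right-hand side (vector or matrix).
#' @return solution (or inverse of `M`).
#' @keywords internal
#' @noRd
chol_solve <- function(M, b = NULL) {
  stopifnot(is.matrix(M), nrow(M) == ncol(M))
  ch <- tryCatch(chol(M), error = function(e) NULL)
  if (is.null(ch)) {
    jit <- 1e-8 * mean(diag(M))
    if (!is.finite(jit) || jit <= 0) jit <- 1e-8
    ch <- tryCatch(chol(M + diag(jit, nrow(M))), error = function(e) NULL)
    if (is.null(ch)) {
      stop("matrix is not positive definite even after jitter; ",
           "condition suggests duplicated individuals or an unblended G ",
           "(see blend_gw())")
    }
  }
  if (is.null(b)) chol2inv(ch) else backsolve(ch, forwardsolve(t(ch), b))
}

# symmetrize tiny asymmetries from floating point
symmetrize <- function(M) (M + t(M)) / 2

# Polynomial rolling hash (mod 2^31 - 1) of a serialized R object, as hex;
# used to fingerprint run configs in manifests.
config_hash <- function(x) {
  bytes <- as.double(serialize(x, NULL, version = 2))
  h <- 0
  p <- 2147483647
  for (b in bytes) h <- (h * 257 + b + 1) %% p
  sprintf("%08x", as.integer(h))
}

# Pearson correlation that tolerates degenerate input by returning NA
safe_cor <- function(x, y) {
  if (length(x) < 3L || stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y)
}
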