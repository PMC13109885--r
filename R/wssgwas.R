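# Iterative SNP weighting (weighted single-step GWAS): backsolve GEBVs to
# marker effects, square them into variance weights, trace-normalize, rebuild
# the weighted G, and repeat. Also per-window genetic-variance shares.

#' Iterative wssGWAS SNP weighting
#'
#' Implements the weighting loop: start from `D = I`; compute GEBVs
#' `a_hat_g` of the genotyped animals by ssGBLUP; backsolve marker effects
#' `u_hat = D Z' (Z D Z')^-1 a_hat_g` (so that `Z u_hat` reproduces
#' `a_hat_g`); set raw weights `d_i* = u_hat_i^2 * 2 p_i (1 - p_i)`;
#' trace-normalize so `sum(D) = M`; rebuild the weighted `G` and refit the
#' full ssGBLUP. Two iterations is the standard recommendation. The loop
#' restarts at the ssGBLUP refit each iteration (the stronger variant of the
#' procedure).
#'
#' @inheritParams ssgblup
#' @param n_iter number of weighting iterations (default 2).
#' @param vc variance components reused across iterations (estimated from
#'   the pedigree model when omitted).
#' @param A optional precomputed pedigree relationship matrix.
#' @return list of class `gp_wssgwas`: `weights` (final trace-normalized
#'   vector, length M), `u_hat` (marker effects of the final iteration),
#'   `gebv` (final genotyped-animal GEBVs), `history` (per-iteration weight
#'   matrix), `vc`.
#' @export
iterate_weights <- function(pheno, ped, trait, geno, fixed = "batch",
                            covariates = character(0), n_iter = 2,
                            vc = NULL, A = NULL) {
  stopifnot(n_iter >= 1)
  if (is.null(A)) A <- a_matrix(ped)
  dos <- impute_dosages(geno$dosages)
  M <- ncol(dos)
  p <- colMeans(dos) / 2
  two_pq <- 2 * p * (1 - p)
  Z <- sweep(dos, 2L, 2 * p, "-")
  lambda <- sum(two_pq)
  D <- rep(1, M)
  history <- matrix(NA_real_, n_iter, M)
  u_hat <- NULL
  fitg <- NULL
  for (t in seq_len(n_iter)) {
    fitg <- ssgblup(pheno, ped, trait, geno_weighted(geno, dos, D),
                    fixed = fixed, covariates = covariates, vc = vc, A = A)
    vc <- fitg$vc
    a_g <- fitg$gebv[rownames(dos)]
    # backsolve through the *unblended* weighted G of this iteration
    G_t <- tcrossprod(sweep(Z, 2L, sqrt(D), "*")) / lambda
    Ginv_a <- chol_solve(symmetrize(G_t), a_g)
    u_hat <- (D * crossprod(Z, Ginv_a)[, 1]) / lambda
    if (any(!is.finite(u_hat)))
      stop("non-finite marker effect at marker ",
           colnames(dos)[which(!is.finite(u_hat))[1]])
    d_star <- u_hat^2 * two_pq
    if (any(!is.finite(d_star)))
      stop("non-finite weight at marker ",
           colnames(dos)[which(!is.finite(d_star))[1]])
    D <- normalize_weights(d_star)
    history[t, ] <- D
  }
  structure(list(weights = D, u_hat = u_hat,
                 gebv = fitg$gebv[rownames(dos)],
                 history = history, vc = vc,
                 freqs = p, Z = Z),
            class = "gp_wssgwas")
}

# wrap a weighted-dosage view without copying the map
geno_weighted <- function(geno, dos, D) {
  g <- genotype_matrix_raw(dos, geno$map)
  attr(g, "snp_weights") <- D
  g
}

#' Per-window genetic variance shares
#'
#' Splits the map into non-overlapping windows of `window_snps` consecutive
#' SNPs (a final partial window is allowed) and reports, for each window,
#' `var(Z_w u_w) / var(Z u)`: the variance of the window's contribution to
#' the genomic values across genotyped individuals relative to the variance
#' of the total. Shares are nonnegative; they need not sum to one because
#' window contributions covary.
#'
#' @param state `gp_wssgwas` from [iterate_weights()].
#' @param window_snps SNPs per window (default 20).
#' @return data.frame: `window`, `first`, `last`, `chr`, `share`.
#' @export
window_variance <- function(state, window_snps = 20) {
  Z <- state$Z
  u <- state$u_hat
  M <- ncol(Z)
  if (M < window_snps) {
    warning("fewer markers than one window; reporting a single window")
    window_snps <- M
  }
  total <- stats::var(as.vector(Z %*% u))
  starts <- seq(1L, M, by = window_snps)
  share <- vapply(starts, function(s) {
    idx <- s:min(s + window_snps - 1L, M)
    v <- stats::var(as.vector(Z[, idx, drop = FALSE] %*% u[idx]))
    if (total > 0) v / total else 0
  }, numeric(1))
  data.frame(window = seq_along(starts), first = starts,
             last = pmin(starts + window_snps - 1L, M),
             share = share)
}
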