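# Variance components (EM-REML), Henderson mixed-model equations, and the
# four linear predictors: ABLUP (corrected phenotypes), GBLUP, ssGBLUP and
# WGBLUP.

#' EM-REML variance components for a single-random-effect animal model
#'
#' Fits `y = X b + u + e` with `u ~ N(0, K sigma_g^2)`,
#' `e ~ N(0, I sigma_e^2)` by EM-REML: the expected-quadratic-form updates
#' are iterated until the relative change of both components falls below
#' `tol` or `max_iter` iterations are reached. Computation is carried out in
#' the eigenbasis of `K`, so each iteration costs `O(n p^2)`.
#'
#' @param y numeric response (one record per row of `K`).
#' @param X fixed-effect design matrix (full column rank); `NULL` for
#'   intercept-only.
#' @param K PSD relationship matrix among the record-bearing individuals.
#' @param tol relative convergence tolerance (default 1e-6).
#' @param max_iter iteration cap (default 200).
#' @return list of class `gp_varcomp`: `sigma_g2`, `sigma_e2`, `h2`,
#'   `converged`, `iterations`, `aliased` (`TRUE` when `K` is numerically a
#'   scaled identity so the two components are not separable).
#' @export
em_reml <- function(y, X = NULL, K, tol = 1e-6, max_iter = 200) {
  n <- length(y)
  if (is.null(X)) X <- matrix(1, n, 1)
  stopifnot(nrow(X) == n, nrow(K) == n)
  if (qr(X)$rank < ncol(X)) stop("X is rank deficient")
  aliased <- max(abs(K - diag(mean(diag(K)), n))) < 1e-10
  ols <- stats::lm.fit(X, y)
  vres <- stats::var(ols$residuals)
  if (!is.finite(vres) || vres < 1e-12)
    return(new_varcomp(0, 0, TRUE, 0L, aliased))
  eg <- eigen(symmetrize(K), symmetric = TRUE)
  d <- pmax(eg$values, 0)
  yt <- crossprod(eg$vectors, y)
  Xt <- crossprod(eg$vectors, X)
  sg <- se <- vres / 2
  conv <- FALSE
  it <- 0L
  for (it in seq_len(max_iter)) {
    w <- 1 / (d * sg + se)
    WX <- Xt * w
    XtWX <- crossprod(Xt, WX)
    b <- solve(XtWX, crossprod(WX, yt))
    py <- w * (yt - Xt %*% b)           # rotated P y
    Binv <- solve(XtWX)
    trP <- sum(w) - sum(Binv * crossprod(Xt * w, Xt * w))
    trPK <- sum(w * d) - sum(Binv * crossprod(Xt * w, Xt * (w * d)))
    sg_new <- max(sg + sg^2 * (sum(d * py^2) - trPK) / n, 0)
    se_new <- max(se + se^2 * (sum(py^2) - trP) / n, 1e-12 * vres)
    delta <- max(abs(sg_new - sg) / max(sg, 1e-12),
                 abs(se_new - se) / max(se, 1e-12))
    sg <- sg_new; se <- se_new
    if (delta < tol) { conv <- TRUE; break }
  }
  new_varcomp(sg, se, conv, it, aliased)
}

new_varcomp <- function(sg, se, converged, iterations, aliased = FALSE) {
  structure(list(sigma_g2 = sg, sigma_e2 = se,
                 h2 = if (sg + se > 0) sg / (sg + se) else 0,
                 converged = converged, iterations = iterations,
                 aliased = aliased),
            class = "gp_varcomp")
}

#' @export
print.gp_varcomp <- function(x, ...) {
  cat(sprintf("variance components: sigma_g2 = %.6g, sigma_e2 = %.6g, h2 = %.4f%s\n",
              x$sigma_g2, x$sigma_e2, x$h2,
              if (!x$converged) " (NOT converged)" else ""))
  if (x$aliased) cat("note: K ~ identity, components not separable\n")
  invisible(x)
}

#' Solve Henderson's mixed-model equations
#'
#' Solves
#' \deqn{[X'X, X'Z; Z'X, Z'Z + \lambda K^{-1}] [b; u] = [X'y; Z'y]}
#' with \eqn{\lambda = \sigma_e^2 / \sigma_g^2}, where `Z` is the incidence
#' matrix mapping the `length(y)` records to the individuals indexed by `K`.
#' Returns BLUE fixed effects and BLUP random effects for *all* individuals
#' in `K`, whether or not they carry a record.
#'
#' @param y records.
#' @param X fixed-effect design (`NULL` = intercept-only; a no-fixed-effect
#'   fit is requested with a zero-column matrix).
#' @param K relationship matrix over all individuals (supply either this or
#'   `Kinv`).
#' @param Kinv precomputed inverse relationship matrix (e.g. the single-step
#'   H-inverse).
#' @param vc `gp_varcomp` (or list with `sigma_g2`, `sigma_e2`).
#' @param obs integer (or id) indices into `K`'s order marking which
#'   individual each record belongs to; defaults to `1:length(y)`.
#' @return list of class `gp_mmfit`: `b`, `u` (named by `K`'s ids when
#'   available), `e` (per record), `obs`, `vc`.
#' @export
solve_mme <- function(y, X = NULL, K = NULL, Kinv = NULL, vc,
                      obs = seq_along(y)) {
  n_rec <- length(y)
  if (is.null(X)) X <- matrix(1, n_rec, 1)
  stopifnot(nrow(X) == n_rec)
  if (vc$sigma_e2 <= 0) stop("sigma_e2 must be positive")
  if (vc$sigma_g2 <= 0) stop("sigma_g2 must be positive for BLUP (got 0); ",
                             "use the OLS limit directly")
  if (is.null(Kinv)) {
    stopifnot(!is.null(K))
    Kinv <- chol_solve(symmetrize(unclass(K)))
    dimnames(Kinv) <- dimnames(K)
  }
  n_ind <- nrow(Kinv)
  if (is.character(obs)) obs <- match(obs, rownames(Kinv))
  stopifnot(length(obs) == n_rec, all(obs >= 1 & obs <= n_ind))
  lambda <- vc$sigma_e2 / vc$sigma_g2
  p <- ncol(X)
  # Z'Z is diagonal with record counts; build crossproducts by indexing
  ZtZ <- diag(tabulate(obs, n_ind), n_ind)
  XtZ <- matrix(0, p, n_ind)
  Zty <- numeric(n_ind)
  if (p > 0) for (j in seq_len(p)) XtZ[j, ] <- tabulate2(obs, X[, j], n_ind)
  Zty <- tabulate2(obs, y, n_ind)
  C <- rbind(cbind(crossprod(X), XtZ),
             cbind(t(XtZ), ZtZ + lambda * Kinv))
  rhs <- c(crossprod(X, y), Zty)
  sol <- tryCatch(solve(C, rhs), error = function(err) {
    stop("singular MME coefficient matrix (reciprocal condition number ",
         format(rcond(C), digits = 3), ")")
  })
  b <- sol[seq_len(p)]
  u <- sol[p + seq_len(n_ind)]
  names(u) <- rownames(Kinv)
  e <- y - (if (p > 0) as.vector(X %*% b) else 0) - u[obs]
  structure(list(b = b, u = u, e = e, obs = obs, vc = vc),
            class = "gp_mmfit")
}

# sum of v within groups g (1..n)
tabulate2 <- function(g, v, n) {
  out <- numeric(n)
  agg <- rowsum(v, g)
  out[as.integer(rownames(agg))] <- agg
  out
}

#' Corrected phenotypes from pedigree BLUP
#'
#' Fits the animal model `y = X b + gamma W + Z a + e` with the pedigree
#' relationship matrix A (EM-REML variance components, then Henderson MME)
#' and returns the corrected phenotype `yc = a_hat + e_hat`, i.e. the record
#' minus all estimated fixed-effect and covariate contributions. `yc` is the
#' response used for genomic prediction, avoiding redundant accounting of
#' parental information.
#'
#' @param pheno data.frame with `id`, the trait column, and the fixed/
#'   covariate columns.
#' @param ped pedigree data.frame (id, sire, dam), topologically ordered.
#' @param trait trait column name.
#' @param fixed character vector of factor fixed-effect columns (default
#'   `"batch"`).
#' @param covariates character vector of numeric covariate columns (e.g.
#'   `c("pc1","pc2","pc3")`).
#' @param vc optional precomputed variance components; estimated by
#'   [em_reml()] on the record-bearing subset of A when omitted.
#' @return list of class `gp_yc`: `yc` (named vector over record-bearing
#'   individuals), `fit` (`gp_mmfit`), `vc`, `ebv` (all pedigree members).
#' @export
ablup_corrected_phenotypes <- function(pheno, ped, trait,
                                       fixed = "batch",
                                       covariates = character(0),
                                       vc = NULL) {
  A <- a_matrix(ped)
  ids <- rownames(A)
  ph <- pheno[!is.na(pheno[[trait]]), , drop = FALSE]
  if (!all(ph$id %in% ids)) stop("phenotyped individuals missing from pedigree")
  y <- ph[[trait]]
  X <- build_design(ph, fixed, covariates)
  obs <- match(ph$id, ids)
  if (is.null(vc)) vc <- em_reml(y, X, K = A[obs, obs, drop = FALSE])
  fit <- solve_mme(y, X, K = A, vc = vc, obs = obs)
  yc <- stats::setNames(fit$u[obs] + fit$e, ph$id)
  structure(list(yc = yc, fit = fit, vc = vc, ebv = fit$u),
            class = "gp_yc")
}

# model matrix for factor fixed effects + numeric covariates (intercept
# included; single-record factor levels draw a warning)
build_design <- function(df, fixed, covariates) {
  terms <- c("1", sprintf("factor(%s)", fixed), covariates)
  for (f in fixed) {
    tab <- table(df[[f]])
    if (any(tab == 1))
      warning("fixed-effect level(s) with a single record in '", f, "': ",
              paste(names(tab)[tab == 1], collapse = ", "))
  }
  stats::model.matrix(stats::as.formula(paste("~", paste(terms, collapse = "+"))),
                      data = df)
}

#' GBLUP / WGBLUP genomic prediction
#'
#' Intercept-only mixed model on corrected phenotypes with a genomic
#' relationship matrix: `yc = mu + g + e`, `g ~ N(0, G sigma_g2)`. WGBLUP is
#' GBLUP with `G` built from a supplied SNP weight vector. `G` is blended
#' with `blend_ref` (identity by default; pass `A22` for the single-step
#' blend) to guarantee invertibility.
#'
#' @param yc named corrected phenotypes of the training individuals (names
#'   must appear in `geno`).
#' @param geno `gp_geno` over all candidates (training + prediction targets);
#'   missing dosages are mean-imputed.
#' @param weights optional SNP weights (length M); `NULL` = unweighted GBLUP.
#' @param vc variance components; estimated by EM-REML on the training block
#'   of G when omitted.
#' @param blend_ref matrix blended into G with weight `1 - tau` (default
#'   identity).
#' @param tau blending weight on G (default 0.95; `tau = 1` disables
#'   blending, e.g. when M > n already makes G full rank).
#' @return list of class `gp_gblup`: `gebv` (all candidates), `fit`, `vc`,
#'   `G` (blended).
#' @export
gblup <- function(yc, geno, weights = NULL, vc = NULL, blend_ref = NULL,
                  tau = 0.95) {
  dos <- impute_dosages(geno$dosages)
  if (!all(names(yc) %in% rownames(dos)))
    stop("training ids absent from genotype matrix")
  if (!is.null(weights) && length(weights) != ncol(dos))
    stop("weights length (", length(weights), ") must equal marker count (",
         ncol(dos), ")")
  G <- g_matrix(dos, weights = weights)
  if (is.null(blend_ref)) blend_ref <- diag(nrow(G))
  Gw <- blend_gw(G, blend_ref, tau = tau)
  dimnames(Gw) <- dimnames(G)
  obs <- match(names(yc), rownames(Gw))
  if (is.null(vc)) vc <- em_reml(yc, NULL, K = Gw[obs, obs, drop = FALSE])
  fit <- solve_mme(yc, NULL, K = Gw, vc = vc, obs = obs)
  structure(list(gebv = fit$u, fit = fit, vc = vc, G = Gw),
            class = "gp_gblup")
}

#' @rdname gblup
#' @export
wgblup <- function(yc, geno, weights, vc = NULL, blend_ref = NULL,
                   tau = 0.95)
  gblup(yc, geno, weights = weights, vc = vc, blend_ref = blend_ref,
        tau = tau)

#' Single-step GBLUP
#'
#' Joint evaluation of genotyped and ungenotyped animals: the animal model
#' of [ablup_corrected_phenotypes()] is solved with the single-step
#' H-inverse, `H^-1 = A^-1 + [0 0; 0 Gw^-1 - A22^-1]`, where
#' `Gw = 0.95 G + 0.05 A22` on the genotyped block. The raw phenotype with
#' fixed effects is the default response. With zero genotyped individuals
#' the model reduces to ABLUP.
#'
#' @inheritParams ablup_corrected_phenotypes
#' @param geno `gp_geno` of the genotyped subset (ids must appear in the
#'   pedigree); `NULL` or zero columns reduces to ABLUP.
#' @param A optional precomputed pedigree relationship matrix (from
#'   [a_matrix()]); avoids recomputation in repeated-CV loops.
#' @return list of class `gp_ssgblup`: `gebv` (all pedigree members), `fit`,
#'   `vc`.
#' @export
ssgblup <- function(pheno, ped, trait, geno = NULL, fixed = "batch",
                    covariates = character(0), vc = NULL, A = NULL) {
  if (is.null(A)) A <- a_matrix(ped)
  ids <- rownames(A)
  gids <- if (is.null(geno)) character(0) else rownames(geno$dosages)
  if (!all(gids %in% ids)) stop("genotyped individuals missing from pedigree")
  ph <- pheno[!is.na(pheno[[trait]]), , drop = FALSE]
  y <- ph[[trait]]
  X <- build_design(ph, fixed, covariates)
  if (is.null(vc)) {
    obs0 <- match(ph$id, ids)
    vc <- em_reml(y, X, K = A[obs0, obs0, drop = FALSE])
  }
  if (length(gids) == 0) {
    fit <- solve_mme(y, X, K = A, vc = vc, obs = match(ph$id, ids))
    return(structure(list(gebv = fit$u, fit = fit, vc = vc),
                     class = "gp_ssgblup"))
  }
  # reorder so the genotyped individuals form the trailing block
  ord <- c(setdiff(ids, gids), gids)
  A <- A[ord, ord]
  gidx <- match(gids, ord)
  Ainv <- chol_solve(A)
  A22 <- A[gidx, gidx, drop = FALSE]
  A22inv <- chol_solve(A22)
  dos <- impute_dosages(geno$dosages)
  G <- g_matrix(dos, weights = attr(geno, "snp_weights"))
  Gw <- blend_gw(G, A22)
  Hinv <- h_inverse(Ainv, A22inv, chol_solve(unclass(Gw)), gidx)
  dimnames(Hinv) <- list(ord, ord)
  fit <- solve_mme(y, X, Kinv = Hinv, vc = vc, obs = match(ph$id, ord))
  structure(list(gebv = fit$u[ids], fit = fit, vc = vc),
            class = "gp_ssgblup")
}
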