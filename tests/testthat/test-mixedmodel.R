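test_that("solve_mme matches closed-form GLS/BLUP on random instances", {
  for (seed in 1:20) {
    set.seed(seed)
    n <- 40
    K <- random_psd(n, seed)
    X <- cbind(1, rnorm(n), rbinom(n, 1, 0.5))
    y <- rnorm(n)
    vc <- list(sigma_g2 = runif(1, 0.2, 2), sigma_e2 = runif(1, 0.2, 2))
    fit <- solve_mme(y, X, K = K, vc = vc)
    V <- K * vc$sigma_g2 + diag(vc$sigma_e2, n)
    Vi <- solve(V)
    b <- solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% y)
    u <- vc$sigma_g2 * K %*% Vi %*% (y - X %*% b)
    expect_equal(fit$b, as.vector(b), tolerance = 1e-8)
    expect_equal(unname(fit$u), as.vector(u), tolerance = 1e-8)
    # record identity y = Xb + u + e
    expect_equal(as.vector(X %*% fit$b) + unname(fit$u) + fit$e, y,
                 tolerance = 1e-10)
  }
})

test_that("solve_mme shrinkage and interpolation limits behave", {
  set.seed(4)
  n <- 30
  K <- random_psd(n, 4)
  X <- cbind(1, rnorm(n))
  y <- rnorm(n)
  ols <- lm.fit(X, y)$coefficients
  fit0 <- solve_mme(y, X, K = K, vc = list(sigma_g2 = 1e-10, sigma_e2 = 1))
  expect_equal(fit0$b, unname(ols), tolerance = 1e-6)
  expect_lt(max(abs(fit0$u)), 1e-8)
  fit1 <- solve_mme(y, X, K = K, vc = list(sigma_g2 = 1, sigma_e2 = 1e-8))
  expect_equal(as.vector(X %*% fit1$b) + unname(fit1$u), y,
               tolerance = 1e-4)
  expect_error(solve_mme(y, X, K = K,
                         vc = list(sigma_g2 = 1, sigma_e2 = 0)), "positive")
})

test_that("solve_mme predicts individuals without records", {
  # records only on individuals 1..20 of a 30-animal K; BLUP for all 30
  set.seed(8)
  n <- 30
  K <- random_psd(n, 8)
  rownames(K) <- colnames(K) <- sprintf("a%02d", 1:n)
  obs <- 1:20
  y <- rnorm(20)
  vc <- list(sigma_g2 = 1, sigma_e2 = 0.5)
  fit <- solve_mme(y, NULL, K = K, vc = vc, obs = obs)
  expect_length(fit$u, n)
  # oracle: GLS intercept, then conditional mean over all individuals
  V <- K[obs, obs] + diag(0.5, 20)
  Vi <- solve(V)
  X <- matrix(1, 20, 1)
  b <- solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% y)
  u_all <- K[, obs] %*% Vi %*% (y - as.vector(X %*% b))
  expect_equal(unname(fit$u), as.vector(u_all), tolerance = 1e-8)
})

test_that("EM-REML recovers variance components and flags degeneracies", {
  # aliasing: K = I
  y <- rnorm(50)
  vc <- em_reml(y, NULL, K = diag(50))
  expect_true(vc$aliased)
  # constant response
  vc0 <- em_reml(rep(2, 40), NULL, K = random_psd(40))
  expect_lt(vc0$sigma_g2, 1e-10)
  expect_lt(vc0$sigma_e2, 1e-10)
  expect_error(em_reml(rnorm(10), matrix(1, 10, 2), K = diag(10)),
               "rank deficient")
  # single-instance recovery sanity at generous tolerance
  set.seed(15)
  n <- 300
  K <- random_psd(n, 15)
  g <- as.vector(t(chol(K + diag(1e-8, n))) %*% rnorm(n)) * sqrt(0.3)
  y <- 1 + g + rnorm(n, 0, sqrt(0.7))
  vc1 <- em_reml(y, NULL, K = K)
  expect_true(vc1$converged)
  expect_lt(abs(vc1$h2 - 0.3), 0.2)
})

test_that("EM-REML increases the REML likelihood along its path", {
  # independent check: the restricted log-likelihood at the EM fixed point
  # is no worse than at the starting value
  set.seed(16)
  n <- 120
  K <- random_psd(n, 16)
  y <- as.vector(t(chol(K + diag(1e-8, n))) %*% rnorm(n)) + rnorm(n)
  X <- matrix(1, n, 1)
  rll <- function(sg, se) {
    V <- sg * K + diag(se, n)
    Vi <- solve(V)
    P <- Vi - Vi %*% X %*% solve(t(X) %*% Vi %*% X, t(X) %*% Vi)
    -0.5 * (determinant(V)$modulus + determinant(t(X) %*% Vi %*% X)$modulus +
            t(y) %*% P %*% y)
  }
  v0 <- var(y) / 2
  fit <- em_reml(y, X, K)
  expect_gte(as.numeric(rll(fit$sigma_g2, fit$sigma_e2)),
             as.numeric(rll(v0, v0)) - 1e-6)
})

test_that("corrected phenotypes equal y minus estimated fixed part", {
  ds <- small_dataset()
  # intercept-only: yc = y - mu_hat elementwise
  ph <- ds$pheno
  res <- ablup_corrected_phenotypes(ph, ds$ped, ds$trait,
                                    fixed = character(0))
  ids <- names(res$yc)
  y <- ph[[ds$trait]][match(ids, ph$id)]
  expect_equal(unname(res$yc), y - res$fit$b[1], tolerance = 1e-10)
  # translation invariance
  ph2 <- ph
  ph2[[ds$trait]] <- ph2[[ds$trait]] + 5
  res2 <- ablup_corrected_phenotypes(ph2, ds$ped, ds$trait,
                                     fixed = character(0), vc = res$vc)
  expect_equal(unname(res2$fit$b[1] - res$fit$b[1]), 5, tolerance = 1e-8)
  expect_equal(res2$yc, res$yc, tolerance = 1e-8)
})

test_that("removing batch effects improves agreement with the heritable part", {
  wins <- 0
  for (s in 1:10) {
    cfg <- sim_config(n_founders = 60, n_generations = 1,
                      matings_per_generation = 30, offspring_per_mating = 5,
                      n_markers = 200, n_chromosomes = 2, n_batches = 4,
                      batch_effect_sd = 0.25, h2 = 0.4,
                      missing_rate_by_generation = 0, seed = 500 + s)
    ds <- simulate_dataset(cfg)
    res <- ablup_corrected_phenotypes(ds$pheno, ds$ped, ds$trait)
    ids <- names(res$yc)
    target <- ds$truth$tbv[ids] + ds$truth$e[ids]
    y <- ds$pheno[[ds$trait]][match(ids, ds$pheno$id)]
    if (cor(res$yc, target) > cor(y, target)) wins <- wins + 1
  }
  expect_gte(wins, 8)
})

test_that("GBLUP equals SNP-BLUP backsolve at matched shrinkage", {
  set.seed(33)
  n <- 100; m <- 300
  dos <- random_dosages(n, m, seed = 33)
  yc <- rnorm(n)
  ycc <- yc - mean(yc)
  sb2 <- 0.01; se2 <- 0.5
  Z <- scale(dos, scale = FALSE)
  snp_blup <- Z %*% solve(crossprod(Z) + diag(se2 / sb2, m),
                          crossprod(Z, ycc))
  p <- colMeans(dos) / 2
  denom <- sum(2 * p * (1 - p))
  G <- g_matrix(dos)
  fit <- solve_mme(ycc, matrix(0, n, 0), K = unclass(G),
                   vc = list(sigma_g2 = sb2 * denom, sigma_e2 = se2))
  expect_equal(unname(fit$u), as.vector(snp_blup), tolerance = 1e-6)
})

test_that("WGBLUP with unit weights reproduces GBLUP exactly", {
  ds <- small_dataset()
  yc <- small_yc()$yc
  yc <- yc[names(yc) %in% rownames(ds$geno$dosages)]
  f1 <- gblup(yc, ds$geno)
  f2 <- wgblup(yc, ds$geno, weights = rep(1, ncol(ds$geno$dosages)),
               vc = f1$vc)
  expect_equal(f1$gebv, f2$gebv)
  expect_error(wgblup(yc, ds$geno, weights = c(1, 2)), "length")
})

test_that("ssGBLUP reduces to ABLUP with zero genotyped individuals", {
  ds <- small_dataset()
  f_ss <- ssgblup(ds$pheno, ds$ped, ds$trait, geno = NULL)
  ph <- ds$pheno[!is.na(ds$pheno[[ds$trait]]), ]
  A <- a_matrix(ds$ped)
  X <- gpeval:::build_design(ph, "batch", character(0))
  fit <- solve_mme(ph[[ds$trait]], X, K = A, vc = f_ss$vc,
                   obs = match(ph$id, rownames(A)))
  expect_equal(f_ss$gebv, fit$u, tolerance = 1e-10)
})

test_that("ssGBLUP with Gw = A22 equals ABLUP predictions", {
  # degenerate single-step: when the genomic matrix carries no information
  # beyond the pedigree, H^-1 = A^-1 and the predictions coincide
  ds <- small_dataset()
  ph <- ds$pheno[!is.na(ds$pheno[[ds$trait]]), ]
  A <- a_matrix(ds$ped)
  gids <- rownames(ds$geno$dosages)
  ord <- c(setdiff(rownames(A), gids), gids)
  Ao <- A[ord, ord]
  gi <- match(gids, ord)
  iA22 <- solve(Ao[gi, gi])
  Hi <- h_inverse(solve(Ao), iA22, iA22, gi)
  dimnames(Hi) <- list(ord, ord)
  vc <- list(sigma_g2 = 0.01, sigma_e2 = 0.03)
  X <- gpeval:::build_design(ph, "batch", character(0))
  f_h <- solve_mme(ph[[ds$trait]], X, Kinv = Hi, vc = vc,
                   obs = match(ph$id, ord))
  f_a <- solve_mme(ph[[ds$trait]], X, K = A, vc = vc,
                   obs = match(ph$id, rownames(A)))
  expect_equal(f_h$u[rownames(A)], f_a$u, tolerance = 1e-8)
})

test_that("GBLUP GEBV accuracy respects the heritability ceiling on held-out
           individuals", {
  accs <- numeric(10)
  for (s in 1:10) {
    cfg <- sim_config(n_founders = 80, n_generations = 1,
                      matings_per_generation = 40, offspring_per_mating = 5,
                      n_markers = 400, n_chromosomes = 4, h2 = 0.3,
                      missing_rate_by_generation = 0, seed = 700 + s)
    ds <- simulate_dataset(cfg)
    ds$geno <- qc_filter(ds$geno)$geno
    yc <- ablup_corrected_phenotypes(ds$pheno, ds$ped, ds$trait)$yc
    yc <- yc[names(yc) %in% rownames(ds$geno$dosages)]
    val <- names(yc)[seq(1, length(yc), by = 5)]
    tr <- setdiff(names(yc), val)
    fit <- gblup(yc[tr], ds$geno)
    accs[s] <- cor(yc[val], fit$gebv[val])
  }
  expect_lt(mean(accs), sqrt(0.3) + 0.05)
  expect_gt(mean(accs), 0.05)
})
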