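test_that("datasets round-trip through both dialects", {
  cfg <- sim_config(n_founders = 4, n_generations = 1,
                    matings_per_generation = 2, offspring_per_mating = 1,
                    n_markers = 10, n_chromosomes = 2,
                    missing_rate_by_generation = 0, seed = 13)
  ds <- simulate_dataset(cfg)
  # PLINK text carries no counted-allele column, so only markers with both
  # alleles observed (guaranteed post-QC) are order-recoverable
  p <- colMeans(ds$geno$dosages) / 2
  poly <- which(p > 0 & p < 1)
  ds$geno <- genotype_matrix(ds$geno$dosages[, poly, drop = FALSE],
                             ds$geno$map[poly, , drop = FALSE])
  for (dialect in c("tsv", "ped")) {
    dir <- withr::local_tempdir()
    paths <- write_dataset(ds, dir, dialect = dialect)
    back <- read_dataset(paths, dialect = dialect)
    expect_equal(unname(back$geno$dosages[rownames(ds$geno$dosages), ]),
                 unname(ds$geno$dosages), ignore_attr = TRUE)
    expect_identical(back$geno$map$marker, ds$geno$map$marker)
    expect_identical(back$ped$id, ds$ped$id)
    expect_identical(back$ped$sire, ds$ped$sire)
    expect_equal(back$pheno[[ds$trait]], ds$pheno[[ds$trait]])
  }
})

test_that("PLINK parsing handles allele order, missing codes and errors", {
  read_plink <- gpeval:::read_plink
  dir <- withr::local_tempdir()
  ped_path <- file.path(dir, "t.ped")
  map_path <- file.path(dir, "t.map")
  writeLines(c("1 snp1 0 100", "1 snp2 0 200"),  map_path)
  writeLines(c("FAM i1 0 0 0 -9 A G A A",
               "FAM i2 0 0 0 -9 G A 0 0",
               "FAM i3 0 0 0 -9 G G A A"), ped_path)
  g <- read_plink(ped_path, map_path)
  # heterozygote "A G" and "G A" both give dosage 1 (counted allele = "A")
  expect_equal(unname(g$dosages[, "snp1"]), c(1, 1, 0))
  expect_true(is.na(g$dosages["i2", "snp2"]))
  # missing excluded from frequency denominators
  expect_equal(mean(g$dosages[, "snp2"], na.rm = TRUE) / 2, 1)
  writeLines(c("FAM i1 0 0 0 -9 A G", "FAM i1 0 0 0 -9 A A"),
             file.path(dir, "dup.ped"))
  writeLines("1 snp1 0 100", file.path(dir, "one.map"))
  expect_error(read_plink(file.path(dir, "dup.ped"),
                          file.path(dir, "one.map")), "duplicated")
  writeLines("FAM i1 0 0 0 -9 A", file.path(dir, "ragged.ped"))
  expect_error(read_plink(file.path(dir, "ragged.ped"),
                          file.path(dir, "one.map")), "expected")
  writeLines(c("FAM i1 0 0 0 -9 A G", "FAM i2 0 0 0 -9 C C"),
             file.path(dir, "tri.ped"))
  expect_error(read_plink(file.path(dir, "tri.ped"),
                          file.path(dir, "one.map")), "allele codes")
})

test_that("QC applies the five rules in order with strict thresholds", {
  set.seed(5)
  n <- 100
  # marker 1: call rate 0.96 -> rule 1; marker 2: MAF 0.04 -> rule 2;
  # marker 3: MAF exactly 0.05 -> retained; marker 4: (50,0,50) -> HWE;
  # marker 5: clean; marker 6: unplaced chromosome
  m1 <- c(rep(NA, 4), rbinom(n - 4, 2, 0.5))
  m2 <- c(rep(1, 8), rep(0, n - 8))            # p = 0.04
  m3 <- c(rep(1, 10), rep(0, n - 10))          # p = 0.05
  m4 <- c(rep(0, 50), rep(2, 50))
  m5 <- rbinom(n, 2, 0.5)
  m6 <- rbinom(n, 2, 0.5)
  dos <- cbind(m1, m2, m3, m4, m5, m6)
  rownames(dos) <- sprintf("i%03d", 1:n)
  colnames(dos) <- paste0("s", 1:6)
  geno <- genotype_matrix(dos, data.frame(
    marker = paste0("s", 1:6), chr = c("1", "1", "1", "2", "2", "0"),
    pos = c(1, 2, 3, 1, 2, 1), a1 = "A", a2 = "B"))
  res <- qc_filter(geno)
  expect_equal(res$report$removed_snp_call_rate, "s1")
  expect_equal(res$report$removed_maf, "s2")
  expect_equal(res$report$removed_hwe, "s4")
  expect_equal(res$report$removed_unplaced, "s6")
  expect_setequal(res$geno$map$marker, c("s3", "s5"))
  expect_equal(res$report$n_snps_in - res$report$n_snps_out, 4)
  # rerunning on its own output removes nothing
  res2 <- qc_filter(res$geno)
  expect_equal(res2$report$n_snps_out, res$report$n_snps_out)
  expect_equal(res2$report$n_ind_out, res$report$n_ind_out)
  # low-call-rate individual removal
  dos2 <- dos[, c(5, 5, 5, 5, 5)] ; colnames(dos2) <- paste0("t", 1:5)
  dos2[1, 1:4] <- NA
  geno2 <- genotype_matrix(dos2, data.frame(marker = paste0("t", 1:5),
                                            chr = "1", pos = 1:5,
                                            a1 = "A", a2 = "B"))
  res3 <- qc_filter(geno2, maf = 0, hwe_p = 0, snp_call_rate = 0.5)
  expect_equal(res3$report$removed_individuals, "i001")
  expect_error(qc_filter(geno, maf = 0.99), "empty panel")
})

test_that("HWE exact test matches a direct enumeration oracle", {
  # oracle: enumerate all heterozygote counts compatible with the allele
  # counts and sum probabilities <= that of the observed configuration
  # Levene's conditional distribution, unnormalized multinomial weights
  # w(h) = 2^h / (h! nAA(h)! nBB(h)!), enumerated over all feasible h
  oracle <- function(nab, naa, nbb) {
    n <- nab + naa + nbb
    na <- 2 * naa + nab
    hets <- seq(na %% 2, min(na, 2 * n - na), by = 2)
    lw <- sapply(hets, function(h) {
      h * log(2) - lgamma(h + 1) - lgamma((na - h) / 2 + 1) -
        lgamma(n - h - (na - h) / 2 + 1)
    })
    pr <- exp(lw - max(lw))
    pr <- pr / sum(pr)
    sum(pr[pr <= pr[match(nab, hets)] + 1e-12])
  }
  cases <- list(c(0, 50, 50), c(25, 25, 50), c(50, 25, 25), c(10, 5, 85),
                c(3, 0, 7))
  for (cs in cases) {
    expect_equal(hwe_exact_test(cs[1], cs[2], cs[3]),
                 oracle(cs[1], cs[2], cs[3]), tolerance = 1e-8)
  }
  expect_lt(hwe_exact_test(0, 50, 50), 1e-6)
  expect_equal(hwe_exact_test(0, 0, 0), 1)
})

test_that("LD pruning collapses duplicates, keeps independents, is monotone", {
  dos <- random_dosages(80, 40, seed = 17)
  dos[, 2] <- dos[, 1]                       # duplicate pair, r2 = 1
  geno <- toy_geno(dos)
  kept <- ld_prune(geno, r2_threshold = 0.2)
  expect_equal(sum(c(1, 2) %in% kept), 1)    # exactly one survivor
  # independent markers: simulate fresh columns, all should survive
  set.seed(99)
  indep <- matrix(rbinom(200 * 30, 2, 0.5), 200, 30)
  r2max <- max(cor(indep)[upper.tri(diag(30))]^2)
  if (r2max < 0.05) {
    kept2 <- ld_prune(toy_geno(indep), r2_threshold = 0.2)
    expect_equal(length(kept2), 30)
  }
  # nested thresholds on one LD-structured panel
  ds <- small_dataset()
  k02 <- ld_prune(ds$geno, r2_threshold = 0.2)
  k04 <- ld_prune(ds$geno, r2_threshold = 0.4)
  k06 <- ld_prune(ds$geno, r2_threshold = 0.6)
  expect_lte(length(k02), length(k04))
  expect_lte(length(k04), length(k06))
  expect_error(ld_prune(geno, r2_threshold = 0), "threshold")
  expect_error(ld_prune(geno, r2_threshold = 1.4), "threshold")
})

test_that("pruned sets have no surviving within-window pair above threshold
           and are invariant to individual order", {
  ds <- small_dataset()
  thr <- 0.3
  kept <- ld_prune(ds$geno, window_snps = 20, step_snps = 5,
                   r2_threshold = thr)
  dos <- impute_dosages(ds$geno$dosages)
  # brute-force scan of all retained pairs within any 20-SNP map window
  for (s in seq(1, ncol(dos) - 1, by = 5)) {
    win <- intersect(s:(s + 19), kept)
    if (length(win) < 2) next
    r2 <- suppressWarnings(cor(dos[, win]))^2
    r2[!is.finite(r2)] <- 0
    expect_lte(max(r2[upper.tri(r2)]), thr)
  }
  perm <- sample(nrow(dos))
  geno_perm <- genotype_matrix(ds$geno$dosages[perm, ], ds$geno$map)
  expect_identical(ld_prune(geno_perm, window_snps = 20, step_snps = 5,
                            r2_threshold = thr), kept)
})

test_that("PC scores match brute-force eigendecomposition and separate
           diverged subpopulations", {
  dos <- random_dosages(20, 50, seed = 23)
  dos[3, ] <- dos[4, ]                        # identical individuals
  geno <- toy_geno(dos)
  res <- compute_pcs(geno, k = 3)
  expect_equal(res$scores[3, ], res$scores[4, ], ignore_attr = TRUE)
  expect_true(all(diff(res$varexp) <= 1e-12))
  expect_lte(sum(res$varexp), 1 + 1e-12)
  # brute force: eigendecomposition of the standardized covariance
  p <- colMeans(dos) / 2
  ok <- p > 0 & p < 1
  X <- scale(dos[, ok], center = 2 * p[ok],
             scale = sqrt(2 * p[ok] * (1 - p[ok])))
  ev <- eigen(tcrossprod(X), symmetric = TRUE)
  for (j in 1:3) {
    ref <- ev$vectors[, j] * sqrt(ev$values[j])
    expect_lt(min(max(abs(res$scores[, j] - ref)),
                  max(abs(res$scores[, j] + ref))), 1e-8)
  }
  expect_error(compute_pcs(geno, k = 0), "positive")
  expect_error(compute_pcs(geno, k = 50), "min")
  # two diverged founder pools -> PC1 separates subpopulations
  mk <- function(seed, p) {
    set.seed(seed)
    matrix(rbinom(40 * 200, 2, rep(p, each = 40)), 40, 200)
  }
  set.seed(77)
  pa <- runif(200, 0.05, 0.95)
  pb <- pmin(pmax(pa + sample(c(-1, 1), 200, TRUE) * 0.35, 0.02), 0.98)
  pool <- rbind(mk(1, pa), mk(2, pb))
  rownames(pool) <- sprintf("x%03d", 1:80)
  pcs <- compute_pcs(toy_geno(pool), k = 2)
  lab <- rep(c(0, 1), each = 40)
  expect_gt(abs(cor(pcs$scores[, 1], lab)), 0.9)
})
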