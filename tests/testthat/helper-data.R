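# Shared fixtures, built in code and memoized across test files.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_env))
    assign(key, force(expr), envir = .fixture_env)
  get(key, envir = .fixture_env)
}

# small two-generation dataset, QC'd, with corrected phenotypes
small_dataset <- function() memo("small_ds", {
  cfg <- sim_config(n_founders = 40, n_generations = 2,
                    matings_per_generation = 15, offspring_per_mating = 4,
                    n_markers = 300, n_chromosomes = 3,
                    missing_rate_by_generation = 0, seed = 7)
  ds <- simulate_dataset(cfg)
  ds$geno <- qc_filter(ds$geno)$geno
  ds
})

small_yc <- function() memo("small_yc", {
  ds <- small_dataset()
  ablup_corrected_phenotypes(ds$pheno, ds$ped, ds$trait)
})

# tiny hand pedigree: 2 founders, full sibs, and an inbred sire x daughter cross
hand_pedigree <- function() {
  data.frame(id = c("f1", "f2", "s1", "s2", "x1"),
             sire = c("0", "0", "f1", "f1", "f1"),
             dam = c("0", "0", "f2", "f2", "s1"),
             stringsAsFactors = FALSE)
}

# random PSD matrix with unit-scale diagonal
random_psd <- function(n, seed = 1) {
  set.seed(seed)
  L <- matrix(rnorm(n * n), n)
  tcrossprod(L) / n + diag(0.1, n)
}

# dosage matrix with controllable frequency, complete
random_dosages <- function(n, m, p = 0.4, seed = 1) {
  set.seed(seed)
  matrix(rbinom(n * m, 2, p), n, m,
         dimnames = list(sprintf("i%03d", seq_len(n)),
                         sprintf("m%03d", seq_len(m))))
}

toy_geno <- function(dos) {
  m <- ncol(dos)
  genotype_matrix(dos, data.frame(marker = colnames(dos) %||%
                                    sprintf("m%03d", seq_len(m)),
                                  chr = "1", pos = seq_len(m) * 100L,
                                  a1 = "A", a2 = "B",
                                  stringsAsFactors = FALSE))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# rebuild a trait over existing genotypes with QTL planted at fixed marker
# indices (mirrors the generator's additive model with known placement)
resim_trait_with_qtl <- function(ped, geno, cfg, qtl) {
  set.seed(cfg$seed + 2L)
  dos <- geno$dosages
  n <- nrow(dos); m <- ncol(dos)
  var_g <- cfg$h2 * cfg$trait_sd^2
  var_e <- (1 - cfg$h2) * cfg$trait_sd^2
  effects <- numeric(m)
  effects[qtl] <- rnorm(length(qtl))
  tbv <- as.vector(dos %*% effects)
  s <- sd(tbv)
  effects <- effects * sqrt(var_g) / s
  tbv <- tbv * sqrt(var_g) / s
  tbv <- tbv - mean(tbv)
  batch <- sample.int(cfg$n_batches, n, replace = TRUE)
  be <- rnorm(cfg$n_batches, 0, cfg$batch_effect_sd)
  e <- rnorm(n, 0, sqrt(var_e))
  y <- cfg$trait_mean + be[batch] + tbv + e
  pheno <- data.frame(id = rownames(dos),
                      generation = ped$generation[match(rownames(dos), ped$id)],
                      batch = factor(batch), y = y, stringsAsFactors = FALSE)
  names(pheno)[names(pheno) == "y"] <- cfg$trait
  list(pheno = pheno,
       truth = list(tbv = setNames(tbv, rownames(dos)), effects = effects,
                    qtl = qtl, e = setNames(e, rownames(dos))))
}
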