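# Forward gene-dropping simulator: multi-generation pedigrees, LD-structured
# genotypes from a mosaic founder haplotype pool, and additive traits with a
# batch fixed effect, target heritability and generation-wise missingness.

# Trait presets patterned on the descriptive statistics of the study
# population (body weight and ultrasound abdominal fat thickness of Wenchang
# chickens at 22/32/45 weeks): mean, SD, narrow-sense h2 and effective record
# count among the 3,737 genotyped birds.
.trait_presets <- data.frame(
  trait = c("bw22", "bw32", "bw45", "aft22", "aft32", "aft45"),
  mean  = c(1.774, 1.905, 1.969, 0.750, 0.698, 0.762),
  sd    = c(0.172, 0.228, 0.276, 0.210, 0.234, 0.213),
  h2    = c(0.155, 0.264, 0.200, 0.175, 0.254, 0.174),
  ne    = c(3434, 3153, 2297, 2365, 2628, 1630),
  stringsAsFactors = FALSE
)

#' Trait presets of the reference chicken population
#'
#' Mean, SD, heritability and effective record count for body weight (`bw*`)
#' and abdominal fat thickness (`aft*`) at 22, 32 and 45 weeks of age.
#'
#' @return data.frame of presets.
#' @export
trait_presets <- function() .trait_presets

#' Simulation configuration
#'
#' Assembles and validates all parameters of the synthetic-data generator.
#' The `"wenchang"` preset emulates the reference population: a 3-generation
#' pedigree of about 4,470 birds whose last two generations (about 3,740
#' birds) are genotyped and phenotyped, with trait moments, heritability and
#' record missingness taken from [trait_presets()].
#'
#' @param preset `NULL` or `"wenchang"`.
#' @param trait trait preset name (see [trait_presets()]); sets `h2`,
#'   `trait_mean`, `trait_sd` and the missingness rate unless overridden.
#' @param n_founders,n_generations,matings_per_generation,offspring_per_mating
#'   pedigree structure; the two last arguments recycle to `n_generations`.
#' @param n_markers,n_chromosomes,morgans_per_chromosome marker panel and
#'   genetic map (markers are spread uniformly over chromosomes).
#' @param maf_range founder minor-allele-frequency interval, within (0, 0.5].
#' @param architecture `"polygenic"` (every marker has an effect) or
#'   `"oligogenic"` (exactly `n_qtl` markers carry `qtl_variance_share` of
#'   the genetic variance, the rest shared by background markers).
#' @param n_qtl,qtl_variance_share oligogenic architecture parameters.
#' @param h2 target narrow-sense heritability in \[0, 1\].
#' @param trait_mean,trait_sd trait location and total phenotypic SD.
#' @param n_batches,batch_effect_sd batch fixed-effect structure.
#' @param missing_rate_by_generation per-generation phenotype missingness in
#'   \[0, 1); recycled over generations. Genotypes are complete (the panel
#'   emulates post-QC data); record loss mirrors culling with age.
#' @param genotyped_generations generations (1-based) whose individuals are
#'   genotyped; defaults to all but the founders.
#' @param seed RNG seed.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(preset = NULL, trait = "bw32",
                       n_founders = 80, n_generations = 2,
                       matings_per_generation = 40, offspring_per_mating = 5,
                       n_markers = 1000, n_chromosomes = 5,
                       morgans_per_chromosome = 1,
                       maf_range = c(0.05, 0.5),
                       architecture = c("polygenic", "oligogenic"),
                       n_qtl = 10, qtl_variance_share = 0.8,
                       h2 = NULL, trait_mean = NULL, trait_sd = NULL,
                       n_batches = 5, batch_effect_sd = NULL,
                       missing_rate_by_generation = NULL,
                       genotyped_generations = NULL,
                       seed = 1L) {
  architecture <- match.arg(architecture)
  tp <- .trait_presets[.trait_presets$trait == trait, ]
  if (nrow(tp) == 0) stop("unknown trait preset: ", trait)
  if (!is.null(preset)) {
    preset <- match.arg(preset, "wenchang")
    # 735 founders; 288 x 8 = 2304 and 205 x 7 = 1435 offspring -> 4,474
    # records, of which generations 2-3 (3,739 birds) are genotyped.
    n_founders <- 735
    n_generations <- 2
    matings_per_generation <- c(288, 205)
    offspring_per_mating <- c(8, 7)
    n_chromosomes <- 10
  }
  if (is.null(h2)) h2 <- tp$h2
  if (is.null(trait_mean)) trait_mean <- tp$mean
  if (is.null(trait_sd)) trait_sd <- tp$sd
  if (is.null(batch_effect_sd)) batch_effect_sd <- 0.3 * trait_sd
  if (is.null(missing_rate_by_generation))
    missing_rate_by_generation <- 1 - tp$ne / 3737
  matings_per_generation <- rep_len(matings_per_generation, n_generations)
  offspring_per_mating <- rep_len(offspring_per_mating, n_generations)
  missing_rate_by_generation <- rep_len(missing_rate_by_generation,
                                        n_generations + 1L)
  if (is.null(genotyped_generations))
    genotyped_generations <- if (n_generations >= 1) seq(2, n_generations + 1)
                             else 1L
  cfg <- list(trait = trait, n_founders = as.integer(n_founders),
              n_generations = as.integer(n_generations),
              matings_per_generation = as.integer(matings_per_generation),
              offspring_per_mating = as.integer(offspring_per_mating),
              n_markers = as.integer(n_markers),
              n_chromosomes = as.integer(n_chromosomes),
              morgans_per_chromosome = morgans_per_chromosome,
              maf_range = maf_range, architecture = architecture,
              n_qtl = as.integer(n_qtl),
              qtl_variance_share = qtl_variance_share,
              h2 = h2, trait_mean = trait_mean, trait_sd = trait_sd,
              n_batches = as.integer(n_batches),
              batch_effect_sd = batch_effect_sd,
              missing_rate_by_generation = missing_rate_by_generation,
              genotyped_generations = as.integer(genotyped_generations),
              seed = as.integer(seed))
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  with(cfg, {
    if (h2 < 0 || h2 > 1) stop("h2 must lie in [0, 1]")
    if (maf_range[1] <= 0 || maf_range[2] > 0.5 || maf_range[1] > maf_range[2])
      stop("maf_range must lie within (0, 0.5]")
    counts <- c(n_founders, n_generations, matings_per_generation,
                offspring_per_mating, n_markers, n_chromosomes, n_batches)
    if (any(counts <= 0)) stop("all counts must be positive")
    if (any(missing_rate_by_generation < 0 | missing_rate_by_generation >= 1))
      stop("missing rates must lie in [0, 1)")
    if (morgans_per_chromosome < 0) stop("genetic length must be >= 0")
  })
  invisible(cfg)
}

#' Simulate a multi-generation pedigree
#'
#' Founders (generation 1) have unknown parents; each later generation is
#' produced by `matings_per_generation` sire-dam pairs sampled without
#' replacement from the previous generation, each pair contributing
#' `offspring_per_mating` offspring. Records are returned in topological
#' order (parents before offspring).
#'
#' @param cfg a [sim_config()].
#' @return data.frame with columns `id`, `sire`, `dam`, `generation`
#'   (`"0"` marks an unknown parent).
#' @export
simulate_pedigree <- function(cfg) {
  set.seed(cfg$seed)
  ids <- sprintf("G1_%04d", seq_len(cfg$n_founders))
  ped <- data.frame(id = ids, sire = "0", dam = "0", generation = 1L,
                    stringsAsFactors = FALSE)
  prev <- ids
  for (g in seq_len(cfg$n_generations)) {
    nm <- cfg$matings_per_generation[g]
    if (2L * nm > length(prev))
      stop("matings_per_generation (", nm, ") exceeds available parent pairs ",
           "in generation ", g)
    pick <- sample(prev, 2L * nm)
    sires <- pick[seq_len(nm)]
    dams <- pick[nm + seq_len(nm)]
    noff <- cfg$offspring_per_mating[g]
    kid_ids <- sprintf("G%d_%04d", g + 1L, seq_len(nm * noff))
    kids <- data.frame(id = kid_ids,
                       sire = rep(sires, each = noff),
                       dam = rep(dams, each = noff),
                       generation = g + 1L, stringsAsFactors = FALSE)
    ped <- rbind(ped, kids)
    prev <- kid_ids
  }
  ped
}

# Marker map: markers uniformly spread over chromosomes, 1-based bp positions
# (1 cM ~ 1 Mb scaling for readability); genetic position in Morgans stored
# alongside for the gene dropper.
make_marker_map <- function(cfg) {
  m <- cfg$n_markers
  chr_sizes <- diff(round(seq(0, m, length.out = cfg$n_chromosomes + 1L)))
  chr <- rep(seq_len(cfg$n_chromosomes), chr_sizes)
  pos_m <- unlist(lapply(chr_sizes, function(k)
    if (k > 0) seq(0, cfg$morgans_per_chromosome, length.out = max(k, 2L))[seq_len(k)]
    else numeric(0)))
  data.frame(marker = sprintf("snp%05d", seq_len(m)),
             chr = as.character(chr),
             pos = as.integer(round(pos_m * 1e8) + seq_len(m)),
             a1 = "A", a2 = "B",
             morgan = pos_m,
             stringsAsFactors = FALSE)
}

# Founder haplotype pool: n_anc ancestral haplotypes drawn per-marker from
# maf_range frequencies, then 2 * n_founders pool haplotypes formed as coarse
# mosaics of the ancestors (geometric segment lengths), which induces
# short-range LD decaying with genetic distance.
simulate_founder_pool <- function(cfg, map, n_anc = 12L, switch_rate = 30) {
  m <- cfg$n_markers
  p <- stats::runif(m, cfg$maf_range[1], cfg$maf_range[2])
  anc <- matrix(stats::rbinom(n_anc * m, 1L, rep(p, each = n_anc)),
                nrow = n_anc, byrow = FALSE)
  nh <- 2L * cfg$n_founders
  pool <- matrix(0L, nh, m)
  new_chrom <- c(TRUE, diff(as.integer(factor(map$chr,
                                              levels = unique(map$chr)))) != 0)
  dgen <- c(0, pmax(diff(map$morgan), 0))
  dgen[new_chrom] <- Inf # independent ancestry across chromosomes
  for (h in seq_len(nh)) {
    switch <- stats::runif(m) < (1 - exp(-switch_rate * dgen))
    switch[1] <- TRUE
    seg <- cumsum(switch)
    anc_idx <- sample.int(n_anc, max(seg), replace = TRUE)[seg]
    pool[h, ] <- anc[cbind(anc_idx, seq_len(m))]
  }
  list(pool = pool, freqs = p)
}

# Drop one gamete: recombine the two parental haplotypes with Poisson
# crossover counts per chromosome and uniform crossover positions.
drop_gamete <- function(h1, h2, map_split, morgans) {
  out <- integer(length(h1))
  for (cs in map_split) {
    nco <- stats::rpois(1L, morgans)
    start <- sample.int(2L, 1L)
    if (nco == 0L || morgans == 0) {
      phase <- rep.int(start, length(cs$idx))
    } else {
      cuts <- sort(stats::runif(nco, 0, morgans))
      phase <- 1L + (start - 1L + findInterval(cs$morgan, cuts)) %% 2L
    }
    src <- ifelse(phase == 1L, h1[cs$idx], h2[cs$idx])
    out[cs$idx] <- src
  }
  out
}

#' Simulate genotypes along a pedigree by gene dropping
#'
#' Founder haplotypes are drawn from a mosaic haplotype pool with the target
#' allele-frequency spectrum and short-range LD; offspring haplotypes are
#' formed by meiosis with Poisson-distributed crossovers on each chromosome.
#' Dosage is the sum of the two haplotypes, so Mendelian consistency holds by
#' construction.
#'
#' @param ped pedigree from [simulate_pedigree()] (topologically ordered).
#' @param cfg a [sim_config()].
#' @return object of class `gp_geno`: list with `dosages` (individuals x
#'   markers integer matrix, id rownames) and `map` (marker, chr, pos,
#'   alleles).
#' @export
simulate_genotypes <- function(ped, cfg) {
  set.seed(cfg$seed + 1L)
  map <- make_marker_map(cfg)
  fp <- simulate_founder_pool(cfg, map)
  n <- nrow(ped)
  m <- cfg$n_markers
  pedn <- normalize_pedigree(ped)
  H1 <- matrix(0L, n, m)
  H2 <- matrix(0L, n, m)
  chr_f <- factor(map$chr, levels = unique(map$chr))
  map_split <- lapply(split(seq_len(m), chr_f), function(idx)
    list(idx = idx, morgan = map$morgan[idx]))
  pool_perm <- sample.int(nrow(fp$pool))
  f <- 0L
  for (i in seq_len(n)) {
    si <- pedn$sire_idx[i]; di <- pedn$dam_idx[i]
    if (si == 0L || di == 0L) {
      H1[i, ] <- fp$pool[pool_perm[(2L * f + 1L - 1L) %% nrow(fp$pool) + 1L], ]
      H2[i, ] <- fp$pool[pool_perm[(2L * f + 2L - 1L) %% nrow(fp$pool) + 1L], ]
      f <- f + 1L
    } else {
      H1[i, ] <- drop_gamete(H1[si, ], H2[si, ], map_split,
                             cfg$morgans_per_chromosome)
      H2[i, ] <- drop_gamete(H1[di, ], H2[di, ], map_split,
                             cfg$morgans_per_chromosome)
    }
  }
  dos <- H1 + H2
  rownames(dos) <- pedn$id
  colnames(dos) <- map$marker
  genotype_matrix(dos, map[, c("marker", "chr", "pos", "a1", "a2")])
}

#' Simulate an additive trait over simulated genotypes
#'
#' Generates `y = mean + batch effect + sum(dosage * effect) + e`. Marker
#' effects are drawn Normal and rescaled so the realized sample variance of
#' the true breeding values equals `h2 * trait_sd^2`; the residual SD is
#' `sqrt(1 - h2) * trait_sd`. Batches are assigned uniformly at random with
#' Normal batch effects. Phenotypes of non-genotyped generations are not
#' produced unless `phenotyped_ids` says otherwise, and generation-wise
#' missingness is applied on top.
#'
#' @param geno `gp_geno` from [simulate_genotypes()].
#' @param ped pedigree data.frame.
#' @param cfg a [sim_config()].
#' @param phenotyped_ids ids eligible for records; defaults to the genotyped
#'   generations of `cfg`.
#' @return list with `pheno` (data.frame id, generation, batch, y; `NA` y =
#'   missing record) and `truth` (list: per-individual `tbv`, per-marker
#'   `effects`, `qtl` indices, residuals `e`).
#' @export
simulate_trait <- function(geno, ped, cfg, phenotyped_ids = NULL) {
  set.seed(cfg$seed + 2L)
  dos <- geno$dosages
  n <- nrow(dos); m <- ncol(dos)
  if (is.null(phenotyped_ids))
    phenotyped_ids <- ped$id[ped$generation %in% cfg$genotyped_generations]
  if (!all(phenotyped_ids %in% rownames(dos)))
    stop("genotypes must cover all phenotyped individuals")
  var_g <- cfg$h2 * cfg$trait_sd^2
  var_e <- (1 - cfg$h2) * cfg$trait_sd^2
  if (cfg$h2 == 1 && cfg$batch_effect_sd > 0)
    warning("h2 = 1 with a nonzero batch effect inflates total variance ",
            "above the genetic variance")
  effects <- numeric(m)
  qtl <- integer(0)
  if (var_g > 0) {
    if (cfg$architecture == "polygenic") {
      effects <- stats::rnorm(m)
      qtl <- seq_len(m)
    } else {
      qtl <- sort(sample.int(m, cfg$n_qtl))
      effects[qtl] <- stats::rnorm(cfg$n_qtl)
      share <- cfg$qtl_variance_share
      if (share < 1) {
        bg <- setdiff(seq_len(m), qtl)
        effects[bg] <- stats::rnorm(length(bg))
        # scale the two groups to split var_g as share : (1 - share)
        tq <- as.vector(dos[, qtl, drop = FALSE] %*% effects[qtl])
        tb <- as.vector(dos[, bg, drop = FALSE] %*% effects[bg])
        sq <- stats::sd(tq); sb <- stats::sd(tb)
        if (sq > 0) effects[qtl] <- effects[qtl] * sqrt(share) / sq
        if (sb > 0) effects[bg] <- effects[bg] * sqrt(1 - share) / sb
      }
    }
    tbv <- as.vector(dos %*% effects)
    s <- stats::sd(tbv)
    if (s > 0) {
      effects <- effects * sqrt(var_g) / s
      tbv <- tbv * sqrt(var_g) / s
    }
  } else {
    tbv <- numeric(n)
  }
  tbv <- tbv - mean(tbv)
  batch <- sample.int(cfg$n_batches, n, replace = TRUE)
  batch_eff <- stats::rnorm(cfg$n_batches, 0, cfg$batch_effect_sd)
  e <- stats::rnorm(n, 0, sqrt(var_e))
  y <- cfg$trait_mean + batch_eff[batch] + tbv + e
  gen <- ped$generation[match(rownames(dos), ped$id)]
  keep <- rownames(dos) %in% phenotyped_ids
  miss_rate <- cfg$missing_rate_by_generation[pmin(gen,
                 length(cfg$missing_rate_by_generation))]
  missing <- stats::runif(n) < miss_rate
  y[!keep | missing] <- NA_real_
  pheno <- data.frame(id = rownames(dos), generation = gen,
                      batch = factor(batch), y = y,
                      stringsAsFactors = FALSE)
  names(pheno)[names(pheno) == "y"] <- cfg$trait
  list(pheno = pheno,
       truth = list(tbv = stats::setNames(tbv, rownames(dos)),
                    effects = effects, qtl = qtl,
                    e = stats::setNames(e, rownames(dos)),
                    batch_eff = batch_eff))
}

#' Simulate a complete dataset
#'
#' Convenience wrapper running [simulate_pedigree()], [simulate_genotypes()]
#' and [simulate_trait()] under one configuration. Genotypes are restricted
#' to the configured genotyped generations, emulating a partially genotyped
#' pedigree.
#'
#' @param cfg a [sim_config()].
#' @return list of class `gp_dataset`: `ped`, `geno` (genotyped individuals
#'   only), `pheno`, `truth`, `trait` (trait column name), `cfg`.
#' @export
simulate_dataset <- function(cfg) {
  ped <- simulate_pedigree(cfg)
  geno_all <- simulate_genotypes(ped, cfg)
  tr <- simulate_trait(geno_all, ped, cfg)
  keep <- ped$id[ped$generation %in% cfg$genotyped_generations]
  geno <- genotype_matrix(geno_all$dosages[keep, , drop = FALSE],
                          geno_all$map)
  structure(list(ped = ped, geno = geno,
                 pheno = tr$pheno[tr$pheno$id %in% keep, ],
                 truth = tr$truth, trait = cfg$trait, cfg = cfg),
            class = "gp_dataset")
}

#' @export
print.gp_dataset <- function(x, ...) {
  cat("gp_dataset:", nrow(x$ped), "pedigree records,",
      nrow(x$geno$dosages), "genotyped x", ncol(x$geno$dosages), "markers,",
      "trait", x$trait, "\n")
  invisible(x)
}
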