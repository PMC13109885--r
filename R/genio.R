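# Dataset I/O (PLINK text .ped/.map, TSV dosage dialect, pedigree CSV,
# phenotype TSV), marker/individual quality control, PLINK-style LD pruning
# and principal-component covariates.

#' Genotype container
#'
#' @param dosages individuals x markers matrix of 0/1/2 dosages (`NA` =
#'   missing), rownames = individual ids, colnames = marker ids.
#' @param map data.frame with columns `marker`, `chr`, `pos`, `a1`, `a2`;
#'   positions must be nondecreasing within a chromosome.
#' @return object of class `gp_geno`.
#' @export
genotype_matrix <- function(dosages, map) {
  stopifnot(is.matrix(dosages), nrow(map) == ncol(dosages),
            all(c("marker", "chr", "pos", "a1", "a2") %in% names(map)))
  if (is.null(rownames(dosages)))
    rownames(dosages) <- sprintf("ind%04d", seq_len(nrow(dosages)))
  if (anyDuplicated(rownames(dosages))) stop("duplicated individual ids")
  if (anyDuplicated(map$marker)) stop("duplicated marker ids")
  colnames(dosages) <- map$marker
  for (ch in unique(map$chr)) {
    p <- map$pos[map$chr == ch]
    if (is.unsorted(p)) stop("positions not nondecreasing on chromosome ", ch)
  }
  ok <- is.na(dosages) | dosages %in% c(0, 1, 2)
  if (!all(ok)) stop("dosages must be 0, 1, 2 or NA")
  structure(list(dosages = dosages, map = map), class = "gp_geno")
}

#' @export
print.gp_geno <- function(x, ...) {
  cat("gp_geno:", nrow(x$dosages), "individuals x", ncol(x$dosages),
      "markers on", length(unique(x$map$chr)), "chromosome(s)\n")
  invisible(x)
}

#' Write a dataset to standard text files
#'
#' Writes genotypes as PLINK text `.ped`/`.map` (space-delimited, `0 0` =
#' missing genotype) or as a TSV dosage table (`id` column + one column per
#' marker, accompanied by a `.map.tsv`), the pedigree as CSV
#' (`id,sire,dam,generation`, `0` = unknown parent) and the phenotype table
#' as TSV with `NA` for missing records.
#'
#' @param dataset a `gp_dataset` (or any list with `geno`, `ped`, `pheno`).
#' @param dir output directory (created if needed).
#' @param basename file stem.
#' @param dialect `"ped"` (PLINK text) or `"tsv"` (dosage table).
#' @return invisibly, the named vector of written paths.
#' @export
write_dataset <- function(dataset, dir, basename = "data",
                          dialect = c("ped", "tsv")) {
  dialect <- match.arg(dialect)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  stem <- file.path(dir, basename)
  paths <- c(ped_csv = paste0(stem, ".pedigree.csv"),
             pheno = paste0(stem, ".pheno.tsv"))
  utils::write.csv(dataset$ped, paths["ped_csv"], row.names = FALSE,
                   quote = FALSE)
  utils::write.table(dataset$pheno, paths["pheno"], sep = "\t",
                     row.names = FALSE, quote = FALSE)
  g <- dataset$geno
  if (dialect == "ped") {
    paths <- c(paths, geno = paste0(stem, ".ped"), map = paste0(stem, ".map"))
    write_plink(g, paste0(stem, ".ped"), paste0(stem, ".map"))
  } else {
    paths <- c(paths, geno = paste0(stem, ".dosage.tsv"),
               map = paste0(stem, ".map.tsv"))
    df <- data.frame(id = rownames(g$dosages), g$dosages,
                     check.names = FALSE, stringsAsFactors = FALSE)
    utils::write.table(df, paths["geno"], sep = "\t", row.names = FALSE,
                       quote = FALSE)
    utils::write.table(g$map[, c("marker", "chr", "pos", "a1", "a2")],
                       paths["map"], sep = "\t", row.names = FALSE,
                       quote = FALSE)
  }
  invisible(paths)
}

write_plink <- function(geno, ped_path, map_path) {
  map <- geno$map
  utils::write.table(data.frame(map$chr, map$marker, 0, map$pos),
                     map_path, sep = " ", row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  dos <- geno$dosages
  n <- nrow(dos)
  a1 <- map$a1; a2 <- map$a2
  lines <- character(n)
  for (i in seq_len(n)) {
    d <- dos[i, ]
    al1 <- ifelse(is.na(d), "0", ifelse(d >= 1, a1, a2))
    al2 <- ifelse(is.na(d), "0", ifelse(d == 2, a1, a2))
    lines[i] <- paste("FAM", rownames(dos)[i], "0", "0", "0", "-9",
                      paste(rbind(al1, al2), collapse = " "))
  }
  writeLines(lines, ped_path)
}

read_plink <- function(ped_path, map_path) {
  map_raw <- utils::read.table(map_path, header = FALSE,
                               col.names = c("chr", "marker", "cm", "pos"),
                               colClasses = c("character", "character",
                                              "numeric", "integer"))
  m <- nrow(map_raw)
  lines <- readLines(ped_path)
  n <- length(lines)
  fields <- strsplit(trimws(lines), "[ \t]+")
  bad <- which(lengths(fields) != 6 + 2 * m)
  if (length(bad))
    stop("parse error in ", ped_path, " line ", bad[1], ": expected ",
         6 + 2 * m, " fields, found ", length(fields[[bad[1]]]))
  fm <- do.call(rbind, fields)
  ids <- fm[, 2]
  if (anyDuplicated(ids))
    stop("parse error in ", ped_path, ": duplicated individual ids")
  G1 <- fm[, seq(7, 6 + 2 * m, by = 2), drop = FALSE]
  G2 <- fm[, seq(8, 6 + 2 * m, by = 2), drop = FALSE]
  dos <- matrix(NA_real_, n, m)
  a1 <- character(m); a2 <- character(m)
  for (j in seq_len(m)) {
    alleles <- sort(setdiff(unique(c(G1[, j], G2[, j])), "0"))
    if (length(alleles) > 2)
      stop("parse error in ", ped_path, ": more than two allele codes (",
           paste(alleles, collapse = ","), ") at marker ", map_raw$marker[j])
    a1[j] <- if (length(alleles) >= 1) alleles[1] else "0"
    a2[j] <- if (length(alleles) == 2) alleles[2] else "0"
    miss <- G1[, j] == "0" | G2[, j] == "0"
    dos[, j] <- ifelse(miss, NA_real_,
                       (G1[, j] == a1[j]) + (G2[, j] == a1[j]))
  }
  rownames(dos) <- ids
  genotype_matrix(dos, data.frame(marker = map_raw$marker, chr = map_raw$chr,
                                  pos = map_raw$pos, a1 = a1, a2 = a2,
                                  stringsAsFactors = FALSE))
}

#' Read a dataset from standard text files
#'
#' Counterpart of [write_dataset()]; round-trips dosages, ids, marker map and
#' pedigree links losslessly. PLINK text files do not record which allele is
#' counted, so the PLINK dialect adopts the convention that the
#' lexicographically first allele code at each marker is counted; a
#' heterozygote yields dosage 1 regardless of allele order, `0 0` is read as
#' missing (excluded from allele-frequency denominators downstream), and the
#' round trip is lossless whenever both alleles are observed and the
#' writer's counted allele sorts first (both always true for post-QC data
#' this package simulates). The TSV dosage dialect is unconditionally
#' lossless.
#'
#' @param paths named vector as returned by [write_dataset()] (`geno`, `map`,
#'   `ped_csv`, `pheno`; `map` unused for the PLINK dialect when alleles are
#'   embedded).
#' @param dialect `"ped"` or `"tsv"`.
#' @return list with `geno` (`gp_geno`), `ped`, `pheno`.
#' @export
read_dataset <- function(paths, dialect = c("ped", "tsv")) {
  dialect <- match.arg(dialect)
  geno <- if (dialect == "ped") {
    read_plink(paths[["geno"]], paths[["map"]])
  } else {
    df <- utils::read.table(paths[["geno"]], sep = "\t", header = TRUE,
                            check.names = FALSE, stringsAsFactors = FALSE)
    map <- utils::read.table(paths[["map"]], sep = "\t", header = TRUE,
                             colClasses = c("character", "character",
                                            "integer", "character",
                                            "character"))
    dos <- as.matrix(df[, -1, drop = FALSE])
    rownames(dos) <- df$id
    if (!identical(colnames(dos), map$marker))
      stop("parse error: dosage columns do not match map markers in ",
           paths[["geno"]])
    genotype_matrix(dos, map)
  }
  ped <- NULL
  if (!is.na(paths["ped_csv"]) && file.exists(paths[["ped_csv"]]))
    ped <- utils::read.csv(paths[["ped_csv"]], colClasses = "character")
  pheno <- NULL
  if (!is.na(paths["pheno"]) && file.exists(paths[["pheno"]]))
    pheno <- utils::read.table(paths[["pheno"]], sep = "\t", header = TRUE,
                               stringsAsFactors = FALSE)
  list(geno = geno, ped = ped, pheno = pheno)
}

#' Hardy-Weinberg exact test
#'
#' Two-sided exact test (Wigginton, Cutler & Abecasis 2005; the PLINK
#' default): conditional on the allele counts, the P-value is the total
#' probability of heterozygote counts no more likely than the observed one.
#'
#' @param n_het,n_hom1,n_hom2 genotype counts.
#' @return exact P-value.
#' @export
hwe_exact_test <- function(n_het, n_hom1, n_hom2) {
  n <- n_het + n_hom1 + n_hom2
  if (n == 0) return(1)
  n_rare <- 2 * min(n_hom1, n_hom2) + n_het
  # log-probability of each feasible heterozygote count given allele counts
  hets <- seq(n_rare %% 2, n_rare, by = 2)
  lp <- vapply(hets, function(h) {
    hom_r <- (n_rare - h) / 2
    hom_c <- n - h - hom_r
    lgamma(n + 1) - lgamma(h + 1) - lgamma(hom_r + 1) - lgamma(hom_c + 1) +
      h * log(2) - (lgamma(2 * n + 1) - lgamma(n_rare + 1) -
                    lgamma(2 * n - n_rare + 1))
  }, numeric(1))
  p <- exp(lp - max(lp))
  p <- p / sum(p)
  obs <- match(n_het, hets)
  min(1, sum(p[p <= p[obs] + 1e-12]))
}

#' Marker and individual quality control
#'
#' Applies the panel's standard QC rules in a fixed order: (1) SNP call rate
#' < `snp_call_rate` removed; (2) minor allele frequency strictly below
#' `maf` removed; (3) Hardy-Weinberg exact-test P below `hwe_p` removed;
#' (4) individuals with genotype call rate < `ind_call_rate` removed;
#' (5) markers on the reserved unplaced chromosome label `"0"` removed.
#' A locus removed by an earlier rule is not re-tested by later rules, and
#' statistics for each rule are computed on the data as it stood when the
#' rule ran (allele frequencies use observed, non-missing genotypes only).
#'
#' @param geno `gp_geno`.
#' @param snp_call_rate,maf,hwe_p,ind_call_rate thresholds.
#' @return list with `geno` (filtered) and `report` (removals per rule and
#'   retained counts).
#' @export
qc_filter <- function(geno, snp_call_rate = 0.98, maf = 0.05,
                      hwe_p = 1e-6, ind_call_rate = 0.95) {
  dos <- geno$dosages
  if (length(dos) == 0) stop("empty dosage matrix")
  markers <- geno$map$marker
  keep_m <- rep(TRUE, ncol(dos))

  call_rate <- colMeans(!is.na(dos))
  rm_call <- which(call_rate < snp_call_rate)
  keep_m[rm_call] <- FALSE

  p <- colMeans(dos, na.rm = TRUE) / 2
  maf_obs <- pmin(p, 1 - p)
  rm_maf <- which(keep_m & maf_obs < maf)
  keep_m[rm_maf] <- FALSE

  hwe <- rep(1, ncol(dos))
  idx <- which(keep_m)
  for (j in idx) {
    d <- dos[, j]
    hwe[j] <- hwe_exact_test(sum(d == 1, na.rm = TRUE),
                             sum(d == 0, na.rm = TRUE),
                             sum(d == 2, na.rm = TRUE))
  }
  rm_hwe <- which(keep_m & hwe < hwe_p)
  keep_m[rm_hwe] <- FALSE

  ind_cr <- rowMeans(!is.na(dos[, keep_m, drop = FALSE]))
  rm_ind <- which(ind_cr < ind_call_rate)
  keep_i <- setdiff(seq_len(nrow(dos)), rm_ind)

  rm_chr <- which(keep_m & geno$map$chr == "0")
  keep_m[rm_chr] <- FALSE

  if (!any(keep_m)) stop("empty panel: all SNPs removed by QC")
  out <- genotype_matrix(dos[keep_i, keep_m, drop = FALSE],
                         geno$map[keep_m, , drop = FALSE])
  report <- list(removed_snp_call_rate = markers[rm_call],
                 removed_maf = markers[rm_maf],
                 removed_hwe = markers[rm_hwe],
                 removed_unplaced = markers[rm_chr],
                 removed_individuals = rownames(dos)[rm_ind],
                 n_snps_in = ncol(dos), n_snps_out = sum(keep_m),
                 n_ind_in = nrow(dos), n_ind_out = length(keep_i))
  list(geno = out, report = report)
}

#' Mean-impute missing dosages
#'
#' Replaces missing entries of each marker column by its observed mean
#' dosage, the standard preparation before G construction, pruning, PCA and
#' ML features.
#'
#' @param geno `gp_geno` or plain dosage matrix.
#' @return same type, without missing values.
#' @export
impute_dosages <- function(geno) {
  dos <- if (inherits(geno, "gp_geno")) geno$dosages else geno
  if (anyNA(dos)) {
    mu <- colMeans(dos, na.rm = TRUE)
    idx <- which(is.na(dos), arr.ind = TRUE)
    dos[idx] <- mu[idx[, 2]]
  }
  if (inherits(geno, "gp_geno")) genotype_matrix_raw(dos, geno$map) else dos
}

# constructor bypassing the 0/1/2 integrality check (imputed dosages are
# fractional)
genotype_matrix_raw <- function(dosages, map) {
  structure(list(dosages = dosages, map = map), class = "gp_geno")
}

#' LD pruning with PLINK `--indep-pairwise` semantics
#'
#' Slides a window of `window_snps` markers by `step_snps` along the map
#' order; within each window, whenever a retained pair's squared Pearson
#' correlation of dosages exceeds `r2_threshold`, the member with the lower
#' minor allele frequency is removed (ties: the later map position). The
#' retained set contains no surviving within-window pair above the
#' threshold.
#'
#' @param geno `gp_geno` (missing dosages are mean-imputed for the
#'   correlation computation).
#' @param window_snps,step_snps window geometry (PLINK's 50 and 5).
#' @param r2_threshold squared-correlation threshold in (0, 1].
#' @return integer vector of retained marker indices (map order).
#' @export
ld_prune <- function(geno, window_snps = 50, step_snps = 5, r2_threshold) {
  if (r2_threshold <= 0 || r2_threshold > 1)
    stop("r2_threshold must lie in (0, 1]")
  dos <- impute_dosages(geno$dosages)
  m <- ncol(dos)
  p <- colMeans(dos) / 2
  maf <- pmin(p, 1 - p)
  keep <- rep(TRUE, m)
  starts <- seq(1L, max(1L, m - 1L), by = step_snps)
  for (s in starts) {
    win <- s:min(s + window_snps - 1L, m)
    idx <- win[keep[win]]
    if (length(idx) < 2L) next
    r2 <- suppressWarnings(stats::cor(dos[, idx, drop = FALSE]))^2
    r2[!is.finite(r2)] <- 0
    repeat {
      r2[lower.tri(r2, diag = TRUE)] <- 0
      off <- which(r2 > r2_threshold, arr.ind = TRUE)
      if (nrow(off) == 0L) break
      pair <- idx[off[1L, ]]
      drop <- if (maf[pair[1]] < maf[pair[2]]) pair[1]
              else if (maf[pair[2]] < maf[pair[1]]) pair[2]
              else max(pair)
      keep[drop] <- FALSE
      kpos <- which(idx == drop)
      idx <- idx[-kpos]
      r2 <- r2[-kpos, -kpos, drop = FALSE]
      if (length(idx) < 2L) break
    }
    if (s + window_snps - 1L >= m) break
  }
  which(keep)
}

#' Principal components of the genotype matrix
#'
#' Eigendecomposition of the covariance of centered, standardized dosages
#' (each marker centered by `2p` and scaled by `sqrt(2p(1-p))`), the usual
#' population-structure covariates.
#'
#' @param geno `gp_geno` (mean-imputed internally).
#' @param k number of components, `0 < k < min(n, m)`.
#' @return list with `scores` (n x k, columns `pc1..pck`) and `varexp`
#'   (fraction of total variance per component, nonincreasing).
#' @export
compute_pcs <- function(geno, k = 3) {
  dos <- impute_dosages(geno$dosages)
  if (k <= 0) stop("k must be positive")
  if (k >= min(dim(dos))) stop("k must be < min(n_individuals, n_markers)")
  p <- colMeans(dos) / 2
  ok <- p > 0 & p < 1
  X <- sweep(dos[, ok, drop = FALSE], 2L, 2 * p[ok], "-")
  X <- sweep(X, 2L, sqrt(2 * p[ok] * (1 - p[ok])), "/")
  sv <- svd(X, nu = k, nv = 0)
  scores <- sv$u %*% diag(sv$d[seq_len(k)], k)
  dimnames(scores) <- list(rownames(dos), paste0("pc", seq_len(k)))
  list(scores = scores, varexp = (sv$d^2 / sum(sv$d^2))[seq_len(k)])
}
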