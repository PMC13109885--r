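# Repeated k-fold cross-validation harness and evaluation statistics:
# prediction accuracy (Pearson r), dispersion bias (regression slope), MSE,
# MAE, Bland-Altman agreement, and ANOVA + Tukey HSD model comparison.

#' Repeated k-fold partition plan
#'
#' Uniform random partitions of the ids into `k` folds whose sizes differ by
#' at most one, repeated `repeats` times; deterministic under `seed`.
#'
#' @param ids vector of individual ids.
#' @param k folds per repeat (default 5).
#' @param repeats number of repeats (default 10), for `repeats * k`
#'   validation rounds in total.
#' @param seed RNG seed.
#' @return list of class `gp_foldplan`: `rounds` (list with `repeat_`,
#'   `fold`, `validation` ids per round), `k`, `repeats`, `seed`, `ids`.
#' @export
make_folds <- function(ids, k = 5, repeats = 10, seed = 1) {
  n <- length(ids)
  if (n < k) stop("need at least k ids")
  set.seed(seed)
  rounds <- list()
  for (r in seq_len(repeats)) {
    lab <- sample(rep_len(seq_len(k), n))
    for (f in seq_len(k)) {
      rounds[[length(rounds) + 1L]] <-
        list(repeat_ = r, fold = f, validation = ids[lab == f])
    }
  }
  structure(list(rounds = rounds, k = k, repeats = repeats, seed = seed,
                 ids = ids),
            class = "gp_foldplan")
}

#' Prediction accuracy
#'
#' Pearson correlation between corrected phenotypes and GEBVs in the
#' validation set.
#'
#' @param yc_val,gebv_val paired vectors (at least 3 pairs, both with
#'   nonzero variance).
#' @return Pearson r.
#' @export
accuracy <- function(yc_val, gebv_val) {
  stopifnot(length(yc_val) == length(gebv_val), length(yc_val) >= 3)
  if (stats::sd(yc_val) == 0 || stats::sd(gebv_val) == 0)
    stop("zero variance in accuracy input")
  stats::cor(yc_val, gebv_val)
}

#' Prediction dispersion bias
#'
#' OLS slope of the corrected phenotype on the GEBV in the validation set:
#' 1 is unbiased, below 1 indicates inflated (over-dispersed) predictions.
#'
#' @inheritParams accuracy
#' @return regression slope.
#' @export
bias_slope <- function(yc_val, gebv_val) {
  if (stats::var(gebv_val) == 0) stop("zero variance in GEBVs")
  stats::cov(yc_val, gebv_val) / stats::var(gebv_val)
}

#' Mean squared and mean absolute error
#'
#' `MSE = mean((f - y)^2)`, `MAE = mean(|f - y|)` over the validation set.
#'
#' @param f predictions.
#' @param y observations.
#' @return named vector `c(mse, mae)`.
#' @export
mse_mae <- function(f, y) {
  stopifnot(length(f) == length(y))
  c(mse = mean((f - y)^2), mae = mean(abs(f - y)))
}

#' Bland-Altman agreement statistics
#'
#' Computes the mean difference (bias), the 95% limits of agreement
#' `bias +/- 1.96 sd(diff)`, and the percentage of pairs strictly inside the
#' limits.
#'
#' @param x,y paired measurements (>= 3 pairs).
#' @return list: `bias`, `lower`, `upper`, `pct_within`, `degenerate`
#'   (`TRUE` when the differences have zero spread and the limits collapse).
#' @export
bland_altman <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  d <- x - y
  s <- stats::sd(d)
  bias <- mean(d)
  degenerate <- s < .Machine$double.eps^0.5
  lower <- bias - 1.96 * s
  upper <- bias + 1.96 * s
  pct <- if (degenerate) NA_real_ else 100 * mean(d > lower & d < upper)
  list(bias = bias, lower = lower, upper = upper, pct_within = pct,
       degenerate = degenerate)
}

#' Run repeated cross-validation over a model panel
#'
#' For each validation round the requested models are trained on the
#' remaining folds (variance components re-estimated on the training
#' portion; WGBLUP weights re-learned per fold by default) and evaluated on
#' the held-out fold against the corrected phenotypes: accuracy, dispersion
#' bias, MSE and MAE. Corrected phenotypes are computed once from the full
#' pedigree model, as in routine evaluations. A failing model in a round is
#' recorded as failed and excluded from summaries.
#'
#' @param dataset `gp_dataset` (or list with `ped`, `geno`, `pheno`,
#'   `trait`).
#' @param models subset of `c("ablup", "gblup", "ssgblup", "wgblup", "krr",
#'   "svr", "rf")`.
#' @param k,repeats,seed fold plan (see [make_folds()]); alternatively pass
#'   a prebuilt `plan`.
#' @param plan optional `gp_foldplan` to use verbatim.
#' @param fixed,covariates fixed-effect / covariate columns of the pedigree
#'   model (covariates default to any `pc*` columns present).
#' @param weights_source `"fold"` (default: wssGWAS weights learned inside
#'   each training fold) or `"full"` (learned once on the full data, as when
#'   weights come from a prior full-data GWAS).
#' @param ml_params named list of hyperparameter lists for `krr`, `svr`,
#'   `rf`; defaults to the study's grid-search optima.
#' @param tune_ml when `TRUE`, run [grid_search()] inside each training fold
#'   instead of fixed hyperparameters (slow).
#' @param yc optional precomputed corrected phenotypes (named vector).
#' @return list of class `gp_cvreport`: `rounds` (tidy data.frame: model,
#'   repeat_, fold, n_val, accuracy, bias, mse, mae, failed), `yc`, `plan`,
#'   `models`.
#' @export
run_cv <- function(dataset, models = c("gblup", "ssgblup", "wgblup"),
                   k = 5, repeats = 10, seed = 1, plan = NULL,
                   fixed = "batch", covariates = NULL,
                   weights_source = c("fold", "full"),
                   ml_params = list(), tune_ml = FALSE, yc = NULL) {
  weights_source <- match.arg(weights_source)
  known <- c("ablup", "gblup", "ssgblup", "wgblup", "krr", "svr", "rf")
  stopifnot(all(models %in% known), length(models) >= 1)
  ped <- dataset$ped; geno <- dataset$geno; pheno <- dataset$pheno
  trait <- dataset$trait
  if (is.null(covariates))
    covariates <- grep("^pc[0-9]+$", names(pheno), value = TRUE)
  fixed <- intersect(fixed, names(pheno))

  need_A <- any(models %in% c("ablup", "ssgblup", "wgblup"))
  A <- if (need_A) a_matrix(ped) else NULL
  if (is.null(yc)) {
    ycfit <- ablup_corrected_phenotypes(pheno, ped, trait, fixed = fixed,
                                        covariates = covariates)
    yc <- ycfit$yc
  }
  dos <- impute_dosages(geno$dosages)
  cand <- intersect(rownames(dos), names(yc)) # genotyped, record-bearing
  yc <- yc[cand]
  if (is.null(plan)) plan <- make_folds(cand, k = k, repeats = repeats,
                                        seed = seed)

  G_blend <- NULL
  if (any(models %in% c("gblup", "wgblup"))) {
    G_blend <- blend_gw(g_matrix(dos), diag(nrow(dos)))
    dimnames(G_blend) <- list(rownames(dos), rownames(dos))
  }
  w_full <- NULL
  if ("wgblup" %in% models && weights_source == "full")
    w_full <- iterate_weights(pheno, ped, trait, geno, fixed = fixed,
                              covariates = covariates, A = A)$weights
  Gw_full <- if (!is.null(w_full))
    structure(blend_gw(g_matrix(dos, weights = w_full), diag(nrow(dos))),
              dimnames = list(rownames(dos), rownames(dos)))
  ml_defaults <- list(
    krr = list(kernel = "rbf", lambda = 0.1, gamma = 1e-4),
    svr = list(kernel = "rbf", C = 1, gamma = 1e-4, epsilon = 0.1),
    rf = list(n_trees = 200, max_depth = 10, min_node_size = 5))
  for (fam in names(ml_defaults))
    ml_params[[fam]] <- utils::modifyList(ml_defaults[[fam]],
                                          ml_params[[fam]] %||% list())

  rows <- list()
  for (ri in seq_along(plan$rounds)) {
    rd <- plan$rounds[[ri]]
    val <- rd$validation
    tr <- setdiff(cand, val)
    pheno_tr <- pheno
    pheno_tr[[trait]][pheno_tr$id %in% val] <- NA # mask validation records
    for (mod in models) {
      res <- tryCatch(
        cv_round_model(mod, tr, val, yc, dos, geno, pheno_tr, ped, trait,
                       fixed, covariates, A, G_blend, Gw_full,
                       weights_source, ml_params, tune_ml,
                       seed = seed + 1000L * ri),
        error = function(e) e)
      if (inherits(res, "error")) {
        rows[[length(rows) + 1L]] <-
          data.frame(model = mod, repeat_ = rd$repeat_, fold = rd$fold,
                     n_val = length(val), accuracy = NA_real_,
                     bias = NA_real_, mse = NA_real_, mae = NA_real_,
                     failed = TRUE, message = conditionMessage(res))
        next
      }
      em <- mse_mae(res, yc[val])
      rows[[length(rows) + 1L]] <-
        data.frame(model = mod, repeat_ = rd$repeat_, fold = rd$fold,
                   n_val = length(val),
                   accuracy = accuracy(yc[val], res),
                   bias = bias_slope(yc[val], res),
                   mse = em[["mse"]], mae = em[["mae"]],
                   failed = FALSE, message = "")
    }
  }
  structure(list(rounds = do.call(rbind, rows), yc = yc, plan = plan,
                 models = models, trait = trait),
            class = "gp_cvreport")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# one model, one round: returns GEBV/predictions for the validation ids
cv_round_model <- function(mod, tr, val, yc, dos, geno, pheno_masked, ped,
                           trait, fixed, covariates, A, G_blend, Gw_full,
                           weights_source, ml_params, tune_ml, seed) {
  if (mod %in% c("gblup", "wgblup")) {
    Gm <- G_blend
    if (mod == "wgblup") {
      if (weights_source == "full") {
        Gm <- Gw_full
      } else {
        w <- iterate_weights(pheno_masked, ped, trait, geno, fixed = fixed,
                             covariates = covariates, A = A)$weights
        Gm <- blend_gw(g_matrix(dos, weights = w), diag(nrow(dos)))
        dimnames(Gm) <- dimnames(G_blend)
      }
    }
    tr_i <- match(tr, rownames(Gm))
    vc <- em_reml(yc[tr], NULL, K = Gm[tr_i, tr_i])
    fit <- solve_mme(yc[tr], NULL, K = Gm, vc = vc, obs = tr_i)
    return(fit$u[val])
  }
  if (mod %in% c("ablup", "ssgblup")) {
    g <- if (mod == "ssgblup") geno else NULL
    fit <- ssgblup(pheno_masked, ped, trait, g, fixed = fixed,
                   covariates = covariates, A = A)
    return(fit$gebv[val])
  }
  # ML families on raw dosages
  Xtr <- dos[tr, , drop = FALSE]
  Xval <- dos[val, , drop = FALSE]
  if (tune_ml) {
    gs <- grid_search(mod, Xtr, yc[tr], seed = seed)
    pars <- gs$best
  } else {
    pars <- as.data.frame(ml_params[[mod]], stringsAsFactors = FALSE)
  }
  fit_predict_family(mod, Xtr, yc[tr], Xval, pars, seed = seed)
}

#' Summarize a cross-validation report
#'
#' Mean and standard error of each metric per model over the (non-failed)
#' validation rounds.
#'
#' @param report `gp_cvreport`.
#' @return data.frame: model, n_rounds, and mean/SE per metric.
#' @export
cv_summary <- function(report) {
  ok <- report$rounds[!report$rounds$failed, ]
  out <- do.call(rbind, lapply(split(ok, ok$model), function(d) {
    sumrow <- function(v) c(mean(v), stats::sd(v) / sqrt(length(v)))
    a <- sumrow(d$accuracy); b <- sumrow(d$bias)
    m <- sumrow(d$mse); e <- sumrow(d$mae)
    data.frame(model = d$model[1], n_rounds = nrow(d),
               accuracy = a[1], accuracy_se = a[2],
               bias = b[1], bias_se = b[2],
               mse = m[1], mse_se = m[2],
               mae = e[1], mae_se = e[2])
  }))
  rownames(out) <- NULL
  out[order(-out$accuracy), ]
}

#' Compare models by one-way ANOVA and Tukey HSD
#'
#' One-way ANOVA of a metric across models over the validation rounds,
#' followed by Tukey's honestly-significant-difference test at the given
#' level, with compact letter groups (models sharing a letter do not differ
#' significantly).
#'
#' @param report `gp_cvreport`.
#' @param metric one of `"accuracy"`, `"bias"`, `"mse"`, `"mae"`.
#' @param alpha significance level (default 0.05).
#' @return list: `anova_p`, `tukey` (pairwise data.frame), `letters` (named
#'   character vector).
#' @export
cv_compare <- function(report, metric = "accuracy", alpha = 0.05) {
  ok <- report$rounds[!report$rounds$failed, ]
  ok$model <- factor(ok$model)
  if (nlevels(ok$model) < 2) stop("need at least two models to compare")
  fit <- stats::aov(stats::as.formula(paste(metric, "~ model")), data = ok)
  pval <- summary(fit)[[1]][["Pr(>F)"]][1]
  tk <- stats::TukeyHSD(fit, conf.level = 1 - alpha)$model
  tukey <- data.frame(pair = rownames(tk), diff = tk[, "diff"],
                      p_adj = tk[, "p adj"], row.names = NULL)
  means <- tapply(ok[[metric]], ok$model, mean)
  letters <- tukey_letters(names(sort(means, decreasing = TRUE)), tukey,
                           alpha)
  list(anova_p = pval, tukey = tukey, letters = letters)
}

# compact letter display by the insertion method: walk models from best to
# worst, adding a new letter whenever a model differs significantly from all
# models carrying the current letter
tukey_letters <- function(models_ordered, tukey, alpha) {
  differs <- function(a, b) {
    hit <- tukey$pair %in% c(paste0(a, "-", b), paste0(b, "-", a))
    any(hit) && all(tukey$p_adj[hit] < alpha)
  }
  groups <- list() # each element: character vector of models sharing a letter
  for (m in models_ordered) {
    placed <- FALSE
    for (gi in seq_along(groups)) {
      if (!any(vapply(groups[[gi]], differs, logical(1), b = m))) {
        groups[[gi]] <- c(groups[[gi]], m)
        placed <- TRUE
      }
    }
    if (!placed) groups[[length(groups) + 1L]] <- m
  }
  out <- stats::setNames(rep("", length(models_ordered)), models_ordered)
  for (gi in seq_along(groups))
    for (m in groups[[gi]])
      out[m] <- paste0(out[m], letters[gi])
  out
}
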