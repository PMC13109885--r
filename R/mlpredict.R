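# Machine-learning predictors on raw 0/1/2 dosage features: kernel ridge
# regression (implemented natively), support vector regression (e1071) and
# random forest (ranger), plus an exhaustive grid search with internal
# five-fold cross-validation scored by Pearson correlation.

# Gram matrix between row sets of X and Y
kernel_gram <- function(X, Y, kernel, gamma = NULL) {
  if (kernel == "linear") return(tcrossprod(X, Y))
  if (kernel == "rbf") {
    stopifnot(!is.null(gamma), gamma > 0)
    d2 <- outer(rowSums(X^2), rowSums(Y^2), "+") - 2 * tcrossprod(X, Y)
    return(exp(-gamma * pmax(d2, 0)))
  }
  stop("unsupported kernel: ", kernel)
}

#' Kernel ridge regression
#'
#' Trains `alpha = (K + lambda I)^-1 (y - ybar)` on the training Gram matrix
#' and predicts `k' alpha + ybar` for test rows, with `K` either the linear
#' kernel `x'x` or the Gaussian RBF kernel `exp(-gamma ||x - x'||^2)` on raw
#' dosage features. A numerically non-PD `K + lambda I` gets one jitter
#' retry before erroring.
#'
#' @param X_train,X_test dosage feature matrices (rows = individuals).
#' @param y_train training responses (corrected phenotypes).
#' @param kernel `"linear"` or `"rbf"`.
#' @param lambda ridge regularization (> 0; the study's optimum is 0.1 with
#'   an RBF kernel of gamma 1e-4).
#' @param gamma RBF bandwidth (> 0).
#' @return numeric predictions for `X_test` rows.
#' @export
krr_fit_predict <- function(X_train, y_train, X_test, kernel = "rbf",
                            lambda = 0.1, gamma = 1e-4) {
  stopifnot(lambda > 0, nrow(X_train) == length(y_train))
  K <- kernel_gram(X_train, X_train, kernel, gamma)
  ybar <- mean(y_train)
  alpha <- chol_solve(symmetrize(K) + diag(lambda, nrow(K)), y_train - ybar)
  k_test <- kernel_gram(X_test, X_train, kernel, gamma)
  as.vector(k_test %*% alpha) + ybar
}

#' Support vector regression (epsilon-insensitive)
#'
#' Thin wrapper around [e1071::svm()] (`eps-regression`) on raw dosage
#' features without internal scaling: residuals inside the epsilon tube
#' contribute zero loss, `C` trades complexity against violations.
#'
#' @inheritParams krr_fit_predict
#' @param C cost parameter (> 0).
#' @param epsilon tube half-width (>= 0).
#' @return predictions for `X_test` rows.
#' @export
svr_fit_predict <- function(X_train, y_train, X_test, kernel = "rbf",
                            C = 1, gamma = 1e-4, epsilon = 0.1) {
  ktype <- switch(kernel, rbf = "radial", linear = "linear",
                  stop("unsupported kernel: ", kernel))
  fit <- e1071::svm(x = X_train, y = y_train, type = "eps-regression",
                    kernel = ktype, cost = C, epsilon = epsilon,
                    gamma = if (ktype == "radial") gamma else 1,
                    scale = FALSE, fitted = FALSE)
  if (fit$tot.nSV == 0) {
    # every residual already inside the tube: any constant in the tube is
    # optimal; the training mean is a canonical choice
    return(rep(mean(y_train), nrow(X_test)))
  }
  as.vector(stats::predict(fit, X_test))
}

#' Random forest regression
#'
#' Wrapper around [ranger::ranger()]: the prediction is the arithmetic mean
#' of the per-tree predictions. sklearn-style `min_samples_split` is mapped
#' to ranger's `min.node.size` (its closest node-size control); `max_depth =
#' 0` means unlimited.
#'
#' @inheritParams krr_fit_predict
#' @param n_trees number of trees (study optimum 200).
#' @param max_depth maximum tree depth (study optimum 10; 0 = unlimited).
#' @param min_node_size minimal node size (study's `min_samples_split` 5).
#' @param seed RNG seed for tree bootstraps.
#' @param per_tree when `TRUE`, also return the per-tree prediction matrix.
#' @return predictions for `X_test` rows (or list with `pred`, `per_tree`).
#' @export
rf_fit_predict <- function(X_train, y_train, X_test, n_trees = 200,
                           max_depth = 10, min_node_size = 5, seed = 1,
                           per_tree = FALSE) {
  df <- data.frame(.y = y_train, X_train, check.names = FALSE)
  fit <- ranger::ranger(dependent.variable.name = ".y", data = df,
                        num.trees = n_trees,
                        max.depth = if (max_depth > 0) max_depth else NULL,
                        min.node.size = min_node_size,
                        seed = seed, num.threads = 1)
  newdat <- data.frame(X_test, check.names = FALSE)
  colnames(newdat) <- colnames(df)[-1]
  if (per_tree) {
    pt <- stats::predict(fit, newdat, predict.all = TRUE,
                         num.threads = 1)$predictions
    list(pred = rowMeans(pt), per_tree = pt)
  } else {
    stats::predict(fit, newdat, num.threads = 1)$predictions
  }
}

#' Default hyperparameter grids
#'
#' Grids bracketing the study's grid-search optima (KRR: RBF kernel,
#' lambda 0.1, gamma 1e-4; SVR: RBF, C 1 or 0.1, gamma 1e-4; RF: 200 trees,
#' depth 10, min split 5).
#'
#' @param family `"krr"`, `"svr"` or `"rf"`.
#' @return data.frame of candidate hyperparameter rows.
#' @export
default_grid <- function(family = c("krr", "svr", "rf")) {
  family <- match.arg(family)
  switch(family,
    krr = rbind(expand.grid(kernel = "linear", lambda = c(0.01, 0.1, 1, 10),
                            gamma = NA_real_, stringsAsFactors = FALSE),
                expand.grid(kernel = "rbf", lambda = c(0.01, 0.1, 1, 10),
                            gamma = c(1e-5, 1e-4, 1e-3),
                            stringsAsFactors = FALSE)),
    svr = expand.grid(kernel = "rbf", C = c(0.01, 0.1, 1, 10),
                      gamma = c(1e-5, 1e-4, 1e-3), epsilon = 0.1,
                      stringsAsFactors = FALSE),
    rf = expand.grid(n_trees = c(100, 200, 500), max_depth = c(5, 10, 0),
                     min_node_size = c(2, 5)))
}

# dispatch one fit/predict call for a grid row
fit_predict_family <- function(family, Xtr, ytr, Xte, pars, seed = 1) {
  switch(family,
    krr = krr_fit_predict(Xtr, ytr, Xte, kernel = pars$kernel,
                          lambda = pars$lambda,
                          gamma = if (is.na(pars$gamma)) 1e-4 else pars$gamma),
    svr = svr_fit_predict(Xtr, ytr, Xte, kernel = pars$kernel, C = pars$C,
                          gamma = pars$gamma, epsilon = pars$epsilon),
    rf = rf_fit_predict(Xtr, ytr, Xte, n_trees = pars$n_trees,
                        max_depth = pars$max_depth,
                        min_node_size = pars$min_node_size, seed = seed),
    stop("unknown model family: ", family))
}

#' Exhaustive grid search with internal five-fold cross-validation
#'
#' Evaluates every grid row by k-fold CV inside the training data and picks
#' the candidate with the highest mean Pearson correlation between predicted
#' and observed responses; ties break deterministically in favor of the
#' earlier grid row. Folds with zero response variance are excluded with a
#' warning.
#'
#' @param family `"krr"`, `"svr"` or `"rf"`.
#' @param X,y training features and response.
#' @param grid data.frame of candidates (default [default_grid()]).
#' @param inner_k inner folds (default 5).
#' @param seed fold-assignment seed.
#' @return list: `best` (one-row data.frame), `scores` (grid with mean inner
#'   CV `r` per row).
#' @export
grid_search <- function(family, X, y, grid = default_grid(family),
                        inner_k = 5, seed = 1) {
  stopifnot(nrow(grid) >= 1)
  plan <- make_folds(seq_along(y), k = inner_k, repeats = 1, seed = seed)
  score <- numeric(nrow(grid))
  for (g in seq_len(nrow(grid))) {
    rs <- vapply(seq_len(inner_k), function(f) {
      val <- plan$rounds[[f]]$validation
      tr <- setdiff(seq_along(y), val)
      if (stats::sd(y[val]) == 0) {
        warning("inner fold with zero response variance excluded")
        return(NA_real_)
      }
      pred <- fit_predict_family(family, X[tr, , drop = FALSE], y[tr],
                                 X[val, , drop = FALSE], grid[g, , drop = FALSE],
                                 seed = seed)
      safe_cor(y[val], pred)
    }, numeric(1))
    score[g] <- mean(rs, na.rm = TRUE)
  }
  best <- which.max(score) # ties -> first index
  out <- grid
  out$mean_r <- score
  list(best = grid[best, , drop = FALSE], best_index = best, scores = out)
}
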