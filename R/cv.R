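## ---- Eigenvector-method cross-validation -------------------------------
##
## The held-out prediction never uses the entry it predicts: for a held-out
## row x and variable j, component scores are estimated by least squares
## against the loading matrix with row j removed,
##   t_hat = argmin_t || x_{-j} - P_{-j} t ||^2,   x_hat_j = p_j' t_hat.
## With P'P = I, (P_{-j}' P_{-j}) = I - p_j p_j' and Sherman-Morrison gives
## the closed form x_hat_j = ((P P' x)_j - s_j x_j) / (1 - s_j) with
## s_j = ||p_j||^2, vectorized over rows and variables below.

make_folds <- function(I, n_folds, seed = NULL) {
  n_folds <- as.integer(n_folds)
  if (n_folds < 2L || n_folds > I)
    stop("n_folds must be between 2 and the number of rows")
  if (!is.null(seed)) set.seed(seed)
  sample(rep_len(seq_len(n_folds), I))
}

## weight-based deletion prediction: scores are the model's own linear
## combination t = W'x, computed without the predicted variable,
##   t_hat = W'x - w_j x_j,   x_hat_j = p_j' t_hat.
## Sensitive to shrinkage of W (used for penalty tuning, where the
## loadings-based projection is blind to the ridge).
ev_predict_w <- function(W, P, Xh) {
  A <- (Xh %*% W) %*% t(P)
  s <- rowSums(P * W)                 # p_j . w_j per variable
  Xhat <- A - sweep(Xh, 2L, s, "*")
  attr(Xhat, "rank_fallback") <- FALSE
  Xhat
}

## prediction of every cell of Xh from the other variables of its row
ev_predict <- function(P, Xh) {
  s <- rowSums(P^2)
  denom <- 1 - s
  A <- (Xh %*% P) %*% t(P)
  Xhat <- sweep(A - sweep(Xh, 2L, s, "*"), 2L, denom, "/")
  fallback <- which(denom <= 1e-8)
  for (j in fallback) {       # rank-deficient deletion: pseudo-inverse
    Pj <- P[-j, , drop = FALSE]
    sv <- svd(Pj)
    pos <- sv$d > max(sv$d, 1e-300) * 1e-10
    pinvT <- sv$u[, pos, drop = FALSE] %*%
      (t(sv$v[, pos, drop = FALSE]) / sv$d[pos])
    Th <- Xh[, -j, drop = FALSE] %*% pinvT
    Xhat[, j] <- Th %*% P[j, ]
  }
  attr(Xhat, "rank_fallback") <- length(fallback) > 0L
  Xhat
}

preprocess_fold <- function(X, train, preprocess, block_sizes) {
  Xtr <- X[train, , drop = FALSE]
  Xh <- X[setdiff(seq_len(nrow(X)), train), , drop = FALSE]
  if (preprocess != "none") {
    mbtr <- multiblock(Xtr, block_sizes)
    prm <- preprocess_params(mbtr)
    Xtr <- apply_preprocess(mbtr, prm)$values
    Xh <- apply_preprocess(multiblock(Xh, block_sizes), prm)$values
    if (preprocess == "standardize_block") {
      Xtr <- block_scale(multiblock(Xtr, block_sizes))$values
      Xh <- block_scale(multiblock(Xh, block_sizes))$values
    }
  }
  list(Xtr = Xtr, Xh = Xh)
}

#' Eigenvector-method cross-validated prediction error
#'
#' K-fold cross-validation of a single model specification: rows are
#' partitioned into folds; per fold the model is fitted on the retained
#' rows (with preprocessing re-estimated on those rows only) and every cell
#' of each held-out row is predicted *without using that cell*, by
#' projecting the row's remaining variables onto the training loadings with
#' the corresponding loading row deleted. MPRESS is the mean squared
#' prediction error over all held-out cells; its standard error is the
#' standard deviation of the per-fold means divided by `sqrt(n_folds)`.
#'
#' @param data a [multiblock] object or matrix.
#' @param Q number of components.
#' @param structure,mask optional common/distinctive constraint (see
#'   [scads()]).
#' @param lambda1,lambda2 penalty weights for the per-fold fits.
#' @param n_folds number of folds (default 10).
#' @param seed seed for the fold partition.
#' @param preprocess `"none"` (default; data are used as supplied),
#'   `"standardize"` (per-variable centering/scaling re-estimated on
#'   training rows), or `"standardize_block"` (additionally block scaling).
#' @param folds optional precomputed fold assignment (overrides `seed`).
#' @param score_method how held-out scores are formed: `"loadings"` (the
#'   default; least-squares projection onto the training loadings with the
#'   predicted variable's row deleted) or `"weights"` (the model's own
#'   scoring rule `t = W'x` with the predicted variable deleted; see
#'   [tune_lambda()]). Both are leakage-free: the predicted cell is never
#'   an input to its own prediction.
#' @param return_errors also return the I x J matrix of held-out squared
#'   errors.
#' @param tol,max_iter forwarded to the per-fold fits.
#' @return list with `mpress`, `se`, `fold_mpress`, `rank_fallback` flag,
#'   and (optionally) `errors`.
#' @export
eigenvector_cv <- function(data, Q, structure = NULL, mask = NULL,
                           lambda1 = 0, lambda2 = 0, n_folds = 10L,
                           seed = NULL, preprocess = "none", folds = NULL,
                           score_method = c("loadings", "weights"),
                           return_errors = FALSE, tol = 1e-8,
                           max_iter = 500L) {
  score_method <- match.arg(score_method)
  mb <- as_multiblock(data)
  X <- mb$values
  if (is.character(structure)) structure <- parse_structure(structure, mb$K)
  if (is.null(mask)) {
    mask <- if (!is.null(structure)) structure_mask(structure, mb)
            else matrix(1, ncol(X), Q)
  }
  if (is.null(folds)) folds <- make_folds(nrow(X), n_folds, seed)
  n_folds <- max(folds)
  fit_WP <- function(Xtr) {
    if (all(lambda1 == 0) && lambda2 == 0 && all(mask == 1)) {
      V <- svd(Xtr, nu = 0L, nv = Q)$v       # unpenalized SC model
      list(W = V, P = V)
    } else {
      f <- scads_core(Xtr, Q, mask, lambda1, lambda2, n_starts = 1L,
                      tol = tol, max_iter = max_iter)
      list(W = f$W, P = f$P)
    }
  }
  errs <- if (return_errors) matrix(NA_real_, nrow(X), ncol(X)) else NULL
  fold_means <- numeric(n_folds)
  total_sum <- 0; total_n <- 0
  fallback <- FALSE
  for (f in seq_len(n_folds)) {
    train <- which(folds != f)
    if (length(train) < 2L) stop("fold leaves fewer than 2 training rows")
    pp <- preprocess_fold(X, train, preprocess, mb$blocks$size)
    fm <- fit_WP(pp$Xtr)
    Xhat <- if (score_method == "weights") ev_predict_w(fm$W, fm$P, pp$Xh)
            else ev_predict(fm$P, pp$Xh)
    fallback <- fallback || isTRUE(attr(Xhat, "rank_fallback"))
    e2 <- (pp$Xh - Xhat)^2
    fold_means[f] <- mean(e2)
    total_sum <- total_sum + sum(e2)
    total_n <- total_n + length(e2)
    if (return_errors) errs[folds == f, ] <- e2
  }
  out <- list(mpress = total_sum / total_n,
              se = stats::sd(fold_means) / sqrt(n_folds),
              fold_mpress = fold_means, rank_fallback = fallback,
              folds = folds)
  if (return_errors) out$errors <- errs
  out
}

## ---- candidate tables and the one-standard-error rule -------------------

new_cvtable <- function(label, mpress, se, complexity, n_folds, seed) {
  out <- data.frame(label = label, mpress = mpress, se = se,
                    complexity = complexity, stringsAsFactors = FALSE)
  attr(out, "n_folds") <- n_folds
  attr(out, "seed") <- seed
  class(out) <- c("scads_cvtable", "data.frame")
  out
}

#' @export
print.scads_cvtable <- function(x, ...) {
  cat("Cross-validation table (", attr(x, "n_folds"), "-fold)\n", sep = "")
  print.data.frame(x, row.names = FALSE, digits = 5)
  invisible(x)
}

#' Plot MPRESS with standard-error bars per candidate
#'
#' @param x a CV table as returned by [select_structure()] or
#'   [tune_lambda()].
#' @param ... passed to [graphics::plot()].
#' @export
plot.scads_cvtable <- function(x, ...) {
  ord <- order(x$complexity)
  graphics::plot(seq_along(ord), x$mpress[ord],
                 ylim = range(x$mpress - x$se, x$mpress + x$se),
                 xaxt = "n", xlab = "candidate (simple to complex)",
                 ylab = "MPRESS", pch = 16, ...)
  graphics::axis(1, at = seq_along(ord), labels = x$label[ord], las = 2,
                 cex.axis = 0.7)
  graphics::arrows(seq_along(ord), x$mpress[ord] - x$se[ord],
                   seq_along(ord), x$mpress[ord] + x$se[ord],
                   angle = 90, code = 3, length = 0.03)
  invisible(x)
}

#' The one-standard-error rule
#'
#' Among all candidates whose MPRESS is within one standard error of the
#' minimum-MPRESS candidate, select the simplest; ties on complexity are
#' broken by lower MPRESS, then by label order. `complexity` must be coded
#' so that *smaller values mean simpler models*.
#'
#' @param table a CV table (data frame with `label`, `mpress`, `se`,
#'   `complexity`).
#' @return the row index of the selected candidate, with the selected label
#'   as attribute `"label"`.
#' @export
one_se_rule <- function(table) {
  stopifnot(nrow(table) >= 1L)
  best <- which.min(table$mpress)
  thr <- table$mpress[best] + table$se[best]
  cand <- which(table$mpress <= thr)
  ord <- order(table$complexity[cand], table$mpress[cand],
               as.character(table$label[cand]))
  sel <- cand[ord[1L]]
  structure(sel, label = table$label[sel])
}

## ---- the three sequential selection steps --------------------------------

#' Select the number of components by cross-validation
#'
#' Unconstrained, unpenalized SC models with 1..Q_max components are
#' cross-validated (one SVD per fold serves every Q) and the
#' one-standard-error rule picks the smallest Q whose MPRESS is within one
#' standard error of the minimum.
#'
#' @inheritParams eigenvector_cv
#' @param Q_max largest number of components to consider.
#' @return selected Q, with the full CV table as attribute `"table"`.
#' @export
select_n_components <- function(data, Q_max, n_folds = 10L, seed = NULL,
                                preprocess = "none") {
  mb <- as_multiblock(data)
  X <- mb$values
  Q_max <- as.integer(Q_max)
  if (Q_max > min(nrow(X) - 1L, ncol(X)))
    stop("Q_max must be at most min(I-1, J)")
  folds <- make_folds(nrow(X), n_folds, seed)
  n_folds <- max(folds)
  sums <- matrix(0, n_folds, Q_max)   # per fold, per Q: summed sq. error
  cells <- numeric(n_folds)
  for (f in seq_len(n_folds)) {
    train <- which(folds != f)
    pp <- preprocess_fold(X, train, preprocess, mb$blocks$size)
    V <- svd(pp$Xtr, nu = 0L, nv = Q_max)$v
    cells[f] <- length(pp$Xh)
    for (Q in seq_len(Q_max)) {
      Xhat <- ev_predict(V[, seq_len(Q), drop = FALSE], pp$Xh)
      sums[f, Q] <- sum((pp$Xh - Xhat)^2)
    }
  }
  fold_means <- sweep(sums, 1L, cells, "/")
  tab <- new_cvtable(label = as.character(seq_len(Q_max)),
                     mpress = colSums(sums) / sum(cells),
                     se = apply(fold_means, 2L, stats::sd) / sqrt(n_folds),
                     complexity = seq_len(Q_max), n_folds, seed)
  sel <- one_se_rule(tab)
  structure(as.integer(tab$label[sel]), table = tab)
}

#' Select the common/distinctive structure by cross-validation
#'
#' Every candidate structure (all multisets of Q block subsets, or an
#' explicit candidate list) is cross-validated with `lambda1 = 0` and a
#' fixed small ridge, on the same fold partition; the one-standard-error
#' rule then prefers the structure with the most zero constraints among
#' those within one SE of the minimum MPRESS.
#'
#' Held-out scores are formed through the constrained weights by default
#' (`score_method = "weights"`): the zero blocks that distinguish the
#' candidates live in W, while the loadings are unconstrained, so the
#' loadings-based projection is nearly blind to the candidate structure.
#'
#' @inheritParams eigenvector_cv
#' @param lambda2 ridge used in every candidate fit; default
#'   `1e-6 * sum(X^2) / J` for numerical stability.
#' @param candidates optional list of [structure_template]s; default: all.
#' @param max_candidates hard cap on the enumeration size.
#' @param score_method `"weights"` (default, see Details) or `"loadings"`.
#' @return the selected [structure_template]; attributes `"table"` (the CV
#'   table) and `"best"` (label of the minimum-MPRESS candidate).
#' @export
select_structure <- function(data, Q, lambda2 = NULL, n_folds = 10L,
                             seed = NULL, preprocess = "none",
                             candidates = NULL, max_candidates = 10000L,
                             score_method = c("weights", "loadings"),
                             tol = 1e-8, max_iter = 500L) {
  score_method <- match.arg(score_method)
  mb <- as_multiblock(data)
  X <- mb$values
  if (is.null(candidates)) {
    n_cand <- count_structures(mb$K, Q)
    if (n_cand > max_candidates)
      stop(n_cand, " candidate structures exceed the cap; ",
           "pass an explicit `candidates` list")
    candidates <- enumerate_structures(mb$K, Q)
  }
  labels <- vapply(candidates, structure_label, "")
  if (mb$K == 1L && length(candidates) == 1L)
    return(structure(candidates[[1L]],
                     table = new_cvtable(labels, NA_real_, NA_real_,
                                         ncol(X) * Q, n_folds, seed),
                     best = labels))
  if (is.null(lambda2)) lambda2 <- 1e-6 * sum(X^2) / ncol(X)
  masks <- lapply(candidates, structure_mask, data = mb)
  folds <- make_folds(nrow(X), n_folds, seed)
  n_folds <- max(folds)
  nc <- length(candidates)
  sums <- matrix(0, n_folds, nc)
  cells <- numeric(n_folds)
  for (f in seq_len(n_folds)) {
    train <- which(folds != f)
    pp <- preprocess_fold(X, train, preprocess, mb$blocks$size)
    V <- svd(pp$Xtr, nu = 0L, nv = Q)$v
    cells[f] <- length(pp$Xh)
    for (ci in seq_len(nc)) {
      fit <- scads_core(pp$Xtr, Q, masks[[ci]], lambda1 = 0,
                        lambda2 = lambda2, n_starts = 1L, tol = tol,
                        max_iter = max_iter, W_init = V)
      Xhat <- if (score_method == "weights")
                ev_predict_w(fit$W, fit$P, pp$Xh)
              else ev_predict(fit$P, pp$Xh)
      sums[f, ci] <- sum((pp$Xh - Xhat)^2)
    }
  }
  fold_means <- sweep(sums, 1L, cells, "/")
  free_cells <- vapply(masks, sum, 0)   # fewer free weights = simpler
  tab <- new_cvtable(labels, colSums(sums) / sum(cells),
                     apply(fold_means, 2L, stats::sd) / sqrt(n_folds),
                     complexity = free_cells, n_folds, seed)
  tab$pct_zero <- 100 * (1 - free_cells / (ncol(X) * Q))
  sel <- one_se_rule(tab)
  structure(candidates[[sel]], table = tab,
            best = tab$label[which.min(tab$mpress)])
}

#' Tune a penalty weight by cross-validation
#'
#' Cross-validates the model over a grid of lasso (or ridge) values and
#' applies the one-standard-error rule with "larger penalty = simpler", so
#' the largest penalty within one SE of the minimum MPRESS is returned.
#'
#' @inheritParams eigenvector_cv
#' @param grid numeric vector of candidate penalty values (>= 2 values
#'   unless the grid is a single point). For the lasso, a natural grid runs
#'   from 0 to [lambda_max][tune_lasso_cardinality] of the data.
#' @param which tune `"lasso"` (lambda1) or `"ridge"` (lambda2).
#' @param lambda_other the penalty held fixed (lambda2 when tuning the
#'   lasso and vice versa).
#' @param score_method how held-out scores are formed: `"weights"` (the
#'   default here; `t = W'x` with the predicted variable deleted, so the
#'   MPRESS responds to shrinkage of W — the loadings-based projection is
#'   essentially blind to the ridge, which would make ridge tuning
#'   degenerate) or `"loadings"` (the least-squares projection used
#'   elsewhere).
#' @return the selected penalty value, with the CV table as attribute
#'   `"table"`.
#' @export
tune_lambda <- function(data, Q, structure = NULL, mask = NULL, grid,
                        which = c("lasso", "ridge"), lambda_other = 0,
                        n_folds = 10L, seed = NULL, preprocess = "none",
                        score_method = c("weights", "loadings"),
                        tol = 1e-8, max_iter = 500L) {
  which <- match.arg(which)
  score_method <- match.arg(score_method)
  mb <- as_multiblock(data)
  X <- mb$values
  if (is.character(structure)) structure <- parse_structure(structure, mb$K)
  if (is.null(mask)) {
    mask <- if (!is.null(structure)) structure_mask(structure, mb)
            else matrix(1, ncol(X), Q)
  }
  grid <- sort(unique(as.numeric(grid)))
  folds <- make_folds(nrow(X), n_folds, seed)
  n_folds <- max(folds)
  ng <- length(grid)
  sums <- matrix(0, n_folds, ng)
  cells <- numeric(n_folds)
  for (f in seq_len(n_folds)) {
    train <- which(folds != f)
    pp <- preprocess_fold(X, train, preprocess, mb$blocks$size)
    cells[f] <- length(pp$Xh)
    XtX <- if (which == "lasso" && any(grid > 0)) crossprod(pp$Xtr)
           else NULL
    Wwarm <- NULL
    for (g in seq_len(ng)) {
      l1 <- if (which == "lasso") grid[g] else lambda_other
      l2 <- if (which == "ridge") grid[g] else lambda_other
      fit <- scads_core(pp$Xtr, Q, mask, l1, l2, n_starts = 1L,
                        tol = tol, max_iter = max_iter, XtX = XtX,
                        W_init = Wwarm)
      Wwarm <- fit$W
      Xhat <- if (score_method == "weights") ev_predict_w(fit$W, fit$P, pp$Xh)
              else ev_predict(fit$P, pp$Xh)
      sums[f, g] <- sum((pp$Xh - Xhat)^2)
    }
  }
  fold_means <- sweep(sums, 1L, cells, "/")
  tab <- new_cvtable(formatC(grid, format = "g"),
                     colSums(sums) / sum(cells),
                     apply(fold_means, 2L, stats::sd) / sqrt(n_folds),
                     complexity = -grid,    # larger penalty = simpler
                     n_folds, seed)
  sel <- one_se_rule(tab)
  structure(grid[sel], table = tab)
}

#' Sequential model selection for sparse common/distinctive SCA
#'
#' The three-step strategy: (1) pick the number of components by
#' cross-validating unpenalized SC models; (2) pick the common/distinctive
#' structure by cross-validating every candidate at `lambda1 = 0`; (3) tune
#' the ridge (only when J >= I; with more units than variables the solution
#' is identified and the ridge is set to 0) and then the lasso on a grid
#' from 0 to the data's lambda_max. Each step applies the
#' one-standard-error rule.
#'
#' @inheritParams eigenvector_cv
#' @param Q_max largest number of components considered in step 1.
#' @param lasso_grid_size number of lasso grid points in step 3.
#' @param ridge_grid log-spaced ridge grid for step 3 when J >= I; default
#'   `10^seq(-4, 2) * sum(X^2)/J`.
#' @return an object of class `"scads_selection"`: list with `Q`,
#'   `structure`, `lambda1`, `lambda2`, the final fitted `model`, and the
#'   per-step CV `tables`.
#' @export
sequential_select <- function(data, Q_max, n_folds = 10L, seed = NULL,
                              preprocess = "none", lasso_grid_size = 10L,
                              ridge_grid = NULL) {
  mb <- as_multiblock(data)
  X <- mb$values
  tables <- list()
  Q <- select_n_components(mb, Q_max, n_folds, seed, preprocess)
  tables$n_components <- attr(Q, "table")
  Q <- as.integer(Q)

  tpl <- select_structure(mb, Q, n_folds = n_folds, seed = seed,
                          preprocess = preprocess)
  tables$structure <- attr(tpl, "table")
  mask <- structure_mask(tpl, mb)

  if (nrow(X) > ncol(X)) {
    lambda2 <- 0
  } else {
    if (is.null(ridge_grid))
      ridge_grid <- 10^seq(-4, 2, by = 1) * sum(X^2) / ncol(X)
    lambda2 <- tune_lambda(mb, Q, mask = mask, grid = ridge_grid,
                           which = "ridge", lambda_other = 0,
                           n_folds = n_folds, seed = seed,
                           preprocess = preprocess)
    tables$ridge <- attr(lambda2, "table")
    lambda2 <- as.numeric(lambda2)
  }

  lmax <- lambda_max(X, Q, mask)
  lgrid <- seq(0, lmax, length.out = max(2L, lasso_grid_size))
  lambda1 <- tune_lambda(mb, Q, mask = mask, grid = lgrid, which = "lasso",
                         lambda_other = lambda2, n_folds = n_folds,
                         seed = seed, preprocess = preprocess)
  tables$lasso <- attr(lambda1, "table")
  lambda1 <- as.numeric(lambda1)

  model <- scads(mb, Q = Q, structure = tpl, lambda1 = lambda1,
                 lambda2 = lambda2)
  structure(list(Q = Q, structure = tpl, lambda1 = lambda1,
                 lambda2 = lambda2, model = model, tables = tables),
            class = "scads_selection")
}

#' @export
print.scads_selection <- function(x, ...) {
  cat("Sequential model selection\n")
  cat("  components:", x$Q, "\n")
  cat("  structure: ", structure_label(x$structure), "\n")
  cat("  lambda1 =", signif(x$lambda1, 4),
      " lambda2 =", signif(x$lambda2, 4), "\n\n")
  print(x$model)
  invisible(x)
}
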