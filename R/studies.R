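## Seeded end-to-end simulation studies: parameter recovery under the true
## structure (SCaDS vs concatenated sparse PCA) and common/distinctive
## structure selection by cross-validation.

study_seeds <- function(seed, n_cond, reps, layers = 2L) {
  set.seed(seed)
  array(sample.int(2147483646L, n_cond * reps * layers),
        dim = c(n_cond, reps, layers))
}

## Ridge tuned once per condition by Eigenvector CV with the one-SE rule
## (largest value within one SE), on one dataset, and reused for every
## replication of that condition. Grid: log steps around sum(X^2)/J.
condition_ridge <- function(data, Q, mask, seed, n_folds = 10L) {
  X <- if (inherits(data, "multiblock")) data$values else data
  base <- sum(X^2) / ncol(X)
  grid <- 10^seq(-4, 2) * base
  as.numeric(tune_lambda(data, Q = Q, mask = mask, grid = grid,
                         which = "ridge", n_folds = n_folds, seed = seed))
}

#' Parameter-recovery study
#'
#' For every design condition and replication: generate a dataset, fit the
#' constrained model with the true zero-block mask and a lasso tuned by
#' bisection to the true total number of nonzero weights, fit concatenated
#' sparse PCA (all-ones mask) with per-component correct nonzero counts,
#' and record Tucker congruence and the zero/nonzero classification rate
#' for both. The ridge is tuned once per condition by Eigenvector
#' cross-validation (one-SE rule) on the first replication's dataset and
#' reused for every replication of that condition.
#'
#' @param reps replications per condition; `NULL` uses each condition's
#'   default (20).
#' @param seed integer master seed; replications use independent seeded
#'   substreams, so results are reproducible bit-for-bit.
#' @param setting `"high_dim"` (100 units, two blocks of 250) or
#'   `"low_dim"` (195 units, two blocks of 10).
#' @param conditions optional custom condition list (as returned by
#'   [simulation_conditions()]), e.g. scaled down.
#' @param lambda2 optional fixed ridge value(s), one per condition
#'   (recycled); `NULL` (default) tunes per condition by cross-validation.
#' @param align also record the congruence without component alignment.
#' @return an object of class `"scads_study"`: list with `results` (one row
#'   per condition x replication x method) and `config`.
#' @export
run_recovery_study <- function(reps = NULL, seed = 1L,
                               setting = "high_dim", conditions = NULL,
                               lambda2 = NULL, align = TRUE) {
  if (is.null(conditions)) conditions <- simulation_conditions(setting)
  nc <- length(conditions)
  reps_per <- vapply(conditions, function(cn)
    if (is.null(reps)) cn$replications else as.integer(reps), 0L)
  seeds <- study_seeds(seed, nc, max(reps_per), layers = 2L)
  ridge_used <- numeric(nc)
  rows <- list()
  for (ci in seq_len(nc)) {
    cn <- conditions[[ci]]
    tpl <- parse_structure(cn$template, length(cn$block_sizes))
    mask_true <- structure_mask(tpl, cn$block_sizes)
    Q <- length(tpl)
    for (r in seq_len(reps_per[ci])) {
      sim <- generate_multiblock(cn$I, cn$block_sizes, tpl, cn$sparsity,
                                 cn$noise_fraction, seed = seeds[ci, r, 1])
      X <- sim$data$values
      if (r == 1L) {
        ridge_used[ci] <- if (is.null(lambda2))
          condition_ridge(sim$data, Q, mask_true, seed = seeds[ci, r, 2])
        else rep_len(as.numeric(lambda2), nc)[ci]
      }
      target_tot <- sum(sim$W_true != 0)
      target_pc <- colSums(sim$W_true != 0)

      sc <- tune_lasso_cardinality(sim$data, Q = Q, mask = mask_true,
                                   lambda2 = ridge_used[ci],
                                   target_nonzeros = target_tot)
      sp <- tune_lasso_cardinality(sim$data, Q = Q,
                                   mask = matrix(1, ncol(X), Q),
                                   lambda2 = ridge_used[ci],
                                   target_nonzeros = target_pc,
                                   per_component = TRUE)
      for (m in c("scads", "sparse_pca")) {
        fit <- if (m == "scads") sc$model else sp$model
        rows[[length(rows) + 1L]] <- data.frame(
          condition = cn$name, sparsity = cn$sparsity_level,
          noise = cn$noise_fraction, replication = r, method = m,
          tucker = as.numeric(tucker_congruence(sim$W_true, fit$W,
                                                align = align)),
          tucker_unaligned =
            as.numeric(tucker_congruence(sim$W_true, fit$W, align = FALSE)),
          pct_correct = classification_rate(sim$W_true, fit$W,
                                            align = align),
          nonzeros = sum(fit$W != 0), target_nonzeros = target_tot,
          stringsAsFactors = FALSE)
      }
    }
  }
  results <- do.call(rbind, rows)
  structure(list(results = results,
                 config = list(study = "recovery", seed = seed,
                               setting = setting, reps = reps_per,
                               ridge = ridge_used,
                               conditions = conditions)),
            class = "scads_study")
}

#' Structure-selection study
#'
#' For every condition and replication: generate a dataset with true
#' structure `"D1 D2 C"` and cross-validate all candidate structures
#' (`lambda1 = 0`, fixed small ridge) with the Eigenvector method, then
#' record whether the minimum-MPRESS candidate and the one-standard-error
#' candidate equal the true structure. The ridge is tuned once per
#' condition (as in [run_recovery_study()]) and shared by all candidate
#' fits.
#'
#' @inheritParams run_recovery_study
#' @param setting `"low_dim"` (the setting where the one-SE rule mostly
#'   succeeds) or `"high_dim"` (where selection is known to overfit).
#' @param n_folds folds for the Eigenvector cross-validation.
#' @return `"scads_study"` object; `results` has one row per condition x
#'   replication with the selected labels, `summary` the per-condition
#'   selection proportions.
#' @export
run_structure_study <- function(setting = c("low_dim", "high_dim"),
                                reps = NULL, seed = 1L, conditions = NULL,
                                lambda2 = NULL, n_folds = 10L) {
  setting <- match.arg(setting)
  if (is.null(conditions)) conditions <- simulation_conditions(setting)
  nc <- length(conditions)
  reps_per <- vapply(conditions, function(cn)
    if (is.null(reps)) cn$replications else as.integer(reps), 0L)
  seeds <- study_seeds(seed, nc, max(reps_per), layers = 3L)
  ridge_used <- numeric(nc)
  rows <- list()
  for (ci in seq_len(nc)) {
    cn <- conditions[[ci]]
    tpl <- parse_structure(cn$template, length(cn$block_sizes))
    true_label <- structure_label(tpl)
    mask_true <- structure_mask(tpl, cn$block_sizes)
    Q <- length(tpl)
    for (r in seq_len(reps_per[ci])) {
      sim <- generate_multiblock(cn$I, cn$block_sizes, tpl, cn$sparsity,
                                 cn$noise_fraction, seed = seeds[ci, r, 1])
      if (r == 1L) {
        ridge_used[ci] <- if (is.null(lambda2))
          condition_ridge(sim$data, Q, mask_true, seed = seeds[ci, r, 3],
                          n_folds = n_folds)
        else rep_len(as.numeric(lambda2), nc)[ci]
      }
      sel <- select_structure(sim$data, Q, lambda2 = ridge_used[ci],
                              n_folds = n_folds,
                              seed = seeds[ci, r, 2])
      rows[[length(rows) + 1L]] <- data.frame(
        condition = cn$name, sparsity = cn$sparsity_level,
        noise = cn$noise_fraction, replication = r,
        best_label = attr(sel, "best"),
        onese_label = structure_label(sel),
        best_correct = attr(sel, "best") == true_label,
        onese_correct = structure_label(sel) == true_label,
        stringsAsFactors = FALSE)
    }
  }
  results <- do.call(rbind, rows)
  agg <- stats::aggregate(cbind(best_correct, onese_correct) ~
                            condition + sparsity + noise,
                          data = results, FUN = mean)
  names(agg)[names(agg) == "best_correct"] <- "prop_best"
  names(agg)[names(agg) == "onese_correct"] <- "prop_one_se"
  agg <- agg[order(match(agg$condition,
                         vapply(conditions, `[[`, "", "name"))), ]
  structure(list(results = results, summary = agg,
                 config = list(study = "structure_selection", seed = seed,
                               setting = setting, reps = reps_per,
                               n_folds = n_folds, ridge = ridge_used,
                               conditions = conditions)),
            class = "scads_study")
}

#' @export
print.scads_study <- function(x, ...) {
  cat("Simulation study:", x$config$study,
      "(", x$config$setting, ", seed", x$config$seed, ")\n")
  if (!is.null(x$summary)) {
    cat("Per-condition selection proportions:\n")
    print(x$summary, row.names = FALSE, digits = 3)
  } else {
    agg <- stats::aggregate(tucker ~ condition + method, data = x$results,
                            FUN = stats::median)
    cat("Median Tucker congruence per condition and method:\n")
    print(agg, row.names = FALSE, digits = 3)
  }
  invisible(x)
}
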