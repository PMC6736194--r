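test_that("the criterion value matches direct arithmetic", {
  X <- matrix(c(1, 2, 3, -1, 0, 2), 3, 2)
  W <- matrix(c(0.5, -1, 2, 0.25), 2, 2)
  P <- diag(2)
  # independent elementwise computation
  expect_equal(scads_objective(X, W, P, lambda1 = 1, lambda2 = 2),
               brute_objective(X, W, P, 1, 2))
  # zero weights, no penalties: plain squared norm of X
  expect_equal(scads_objective(X, matrix(0, 2, 2), P), sum(X^2))
  # exact reconstruction gives zero loss
  mb <- make_lowrank(I = 15, block_sizes = c(4, 4), Q = 2, seed = 3)
  Xr <- mb$values
  sv <- svd(Xr, nu = 2, nv = 2)
  Wex <- sv$v %*% diag(1 / sv$d[1:2])
  expect_lt(scads_objective(Xr, Wex, sv$v), 1e-20)
  expect_error(scads_objective(Xr, Wex[1:3, ], sv$v), "dimension")
})

test_that("the loadings update is the reduced-rank Procrustes solution", {
  set.seed(21)
  # orthonormal W and identity data: P equals W
  W <- random_orthonormal(6, 3)
  expect_equal(update_loadings(diag(6), W), W, tolerance = 1e-10)

  # orthonormality always holds
  X <- matrix(rnorm(20 * 6), 20, 6)
  W2 <- matrix(rnorm(12), 6, 2)
  P <- update_loadings(X, W2)
  expect_lt(max(abs(crossprod(P) - diag(2))), 1e-10)

  # minimality against 1000 random column-orthonormal competitors
  obj_star <- scads_objective(X, W2, P)
  objs <- replicate(1000, scads_objective(X, W2, random_orthonormal(6, 2)))
  expect_true(all(obj_star <= objs + 1e-9))

  expect_error(update_loadings(X, matrix(0, 6, 2)), "no active components")
})

test_that("a coordinate update equals the 1-D grid-search minimizer", {
  grid <- seq(-10, 10, by = 1e-4)
  for (seed in 1:100) {
    set.seed(seed)
    X <- matrix(rnorm(6 * 4), 6, 4)
    W <- matrix(rnorm(4 * 2), 4, 2)
    P <- random_orthonormal(4, 2)
    l1 <- runif(1, 0, 5); l2 <- runif(1, 0, 2)
    j <- sample(4, 1); q <- sample(2, 1)
    mask_one <- matrix(0, 4, 2); mask_one[j, q] <- 1
    Wnew <- update_weights(X, P, l1, l2, mask_one, W)
    # untouched cells stay exactly as supplied
    expect_identical(Wnew[-((q - 1) * 4 + j)], W[-((q - 1) * 4 + j)])
    # brute-force the objective along the free coordinate:
    # reconstruction is linear in w, f(w) = ||R0 - w A||^2 + penalties
    W0 <- W; W0[j, q] <- 0
    R0 <- X - X %*% W0 %*% t(P)
    A <- X[, j] %*% t(P[, q])
    f <- sum(R0^2) - 2 * grid * sum(R0 * A) + grid^2 * sum(A^2) +
      l1 * abs(grid) + l2 * grid^2
    expect_lt(abs(Wnew[j, q] - grid[which.min(f)]), 2e-4)
  }
})

test_that("coordinate sweeps respect the mask and the lasso limit", {
  set.seed(5)
  X <- matrix(rnorm(10 * 6), 10, 6)
  mask <- structure_mask(parse_structure("D1 D2 C", 2), c(3, 3))
  P <- random_orthonormal(6, 3)
  W <- matrix(rnorm(18), 6, 3) * mask
  # an overwhelming lasso zeroes every free weight in one sweep
  Wz <- update_weights(X, P, lambda1 = 1e6, lambda2 = 0, mask, W)
  expect_true(all(Wz == 0))
  # masked cells stay bitwise zero over repeated sweeps
  Wk <- W
  for (i in 1:5) Wk <- update_weights(X, P, 0.3, 0.1, mask, Wk)
  expect_identical(Wk[mask == 0], rep(0, sum(mask == 0)))
  expect_error(update_weights(X, X[1:6, 1:3], 0, 0, mask, W),
               "orthonormal")
})

test_that("unpenalized unconstrained fits reach the truncated-SVD optimum", {
  set.seed(7)
  X <- matrix(rnorm(20 * 8), 20, 8)
  fit <- scads(X, Q = 3)
  sv <- svd(X)
  vaf_svd <- 100 * sum(sv$d[1:3]^2) / sum(sv$d^2)
  expect_lt(abs(fit$vaf$total - vaf_svd), 1e-6)
  expect_lt(max(abs(crossprod(fit$P) - diag(3))), 1e-8)
})

test_that("the loss trace never increases", {
  sim <- generate_multiblock(I = 40, block_sizes = c(10, 10),
                             template = "D1 D2 C",
                             sparsity = c(0.2, 0.2, 0.6),
                             noise_fraction = 0.25, seed = 8)
  for (l1 in c(0, 5e-4)) {
    fit <- scads(sim$data, structure = "D1 D2 C", lambda1 = l1,
                 lambda2 = 1e-3)
    expect_gte(length(fit$loss), 2)
    expect_true(all(diff(fit$loss) <= 1e-10 * max(abs(fit$loss), 1)))
    expect_identical(fit$W[fit$mask == 0], rep(0, sum(fit$mask == 0)))
  }
})

test_that("noiseless data with the true mask are recovered", {
  sim <- generate_multiblock(I = 40, block_sizes = c(8, 8),
                             template = "D1 D2 C",
                             sparsity = c(0.2, 0.2, 0.6),
                             noise_fraction = 0, seed = 12)
  expect_equal(sim$data$values %*% sim$W_true, sim$T_true,
               tolerance = 1e-9)
  # unpenalized: the perfect-fit objective is reached ...
  fit0 <- scads(sim$data, structure = "D1 D2 C")
  expect_lt(fit0$objective, 1e-8)
  # ... and a moderate ridge resolves the rotational freedom that the
  # generator's equal-strength components leave in the noiseless fit: the
  # planted weights are the minimum-norm representation, which the ridge
  # singles out
  X <- sim$data$values
  fit <- scads(sim$data, structure = "D1 D2 C",
               lambda2 = 0.05 * sum(X^2) / ncol(X), max_iter = 2000)
  expect_gt(tucker_congruence(sim$W_true, fit$W), 0.99)
})

test_that("sparse_pca is the all-ones-mask special case, field for field", {
  mb <- make_lowrank(I = 20, block_sizes = c(5, 5), noise = 0.2, seed = 13)
  a <- sparse_pca(mb, Q = 2, lambda1 = 1e-3, lambda2 = 1e-3,
                  n_starts = 2, seed = 99)
  b <- scads(mb, Q = 2, mask = matrix(1, 10, 2), lambda1 = 1e-3,
             lambda2 = 1e-3, n_starts = 2, seed = 99)
  expect_identical(a$W, b$W)
  expect_identical(a$P, b$P)
  expect_identical(a$loss, b$loss)
  # no lasso: generically dense weights
  dense <- sparse_pca(mb, Q = 2)
  expect_true(all(dense$W != 0))
})

test_that("a lasso at or above lambda_max empties the model", {
  mb <- make_lowrank(I = 20, block_sizes = c(5, 5), noise = 0.2, seed = 14)
  lmax <- scads:::lambda_max(mb$values, 2, matrix(1, 10, 2))
  fit <- scads(mb, Q = 2, lambda1 = lmax * 1.01)
  expect_true(all(fit$W == 0))
  expect_true(all(fit$empty_components))
  expect_equal(fit$objective, sum(mb$values^2))
})

test_that("bisection tunes the lasso to a nonzero-count target", {
  sim <- generate_multiblock(I = 40, block_sizes = c(10, 10),
                             template = "D1 D2 C",
                             sparsity = c(0.2, 0.2, 0.6),
                             noise_fraction = 0.05, seed = 15)
  mask <- structure_mask(sim$template, c(10, 10))
  n_free <- sum(mask)

  # target everything: essentially no lasso
  full <- tune_lasso_cardinality(sim$data, mask = mask, lambda2 = 1e-4,
                                 target_nonzeros = n_free)
  expect_equal(unname(full$achieved), n_free)
  expect_lt(full$lambda1, 0.1 * full$lambda_max)

  # target nothing: the lambda_max bracket end, all-zero fit
  none <- tune_lasso_cardinality(sim$data, mask = mask, lambda2 = 1e-4,
                                 target_nonzeros = 0)
  expect_equal(unname(none$achieved), 0)
  expect_true(all(none$model$W == 0))

  # a 40%-of-free-entries target (the high-sparsity truth)
  target <- sum(sim$W_true != 0)
  res <- suppressWarnings(
    tune_lasso_cardinality(sim$data, mask = mask, lambda2 = 1e-4,
                           target_nonzeros = target))
  expect_true(res$reached ||
                abs(res$achieved - target) <= max(1, 0.02 * target))
  expect_error(tune_lasso_cardinality(sim$data, mask = mask,
                                      lambda2 = 0, target_nonzeros = 1e6),
               "target_nonzeros")
})

test_that("component scores depend only on nonzero-weight variables", {
  sim <- generate_multiblock(I = 30, block_sizes = c(8, 8),
                             template = "D1 D2 C",
                             sparsity = c(0.2, 0.2, 0.6),
                             noise_fraction = 0.1, seed = 16)
  fit <- scads(sim$data, structure = "D1 D2 C", lambda1 = 2e-4,
               lambda2 = 1e-3)
  X <- sim$data$values
  expect_equal(predict(fit, X), fit$scores)
  expect_equal(predict(fit, matrix(0, 1, 16)), matrix(0, 1, 3),
               ignore_attr = TRUE)
  q <- 3
  zeroed <- which(fit$W[, q] == 0)[1]
  expect_false(is.na(zeroed))
  Xp <- X
  Xp[, zeroed] <- Xp[, zeroed] + 100
  expect_identical(predict(fit, Xp)[, q], fit$scores[, q])
  expect_error(predict(fit, X[, 1:5]), "columns")
})
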