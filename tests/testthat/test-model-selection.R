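test_that("fold assignment is a seeded partition", {
  f <- scads:::make_folds(23, 5, seed = 3)
  expect_length(f, 23)
  expect_setequal(unique(f), 1:5)
  expect_true(all(table(f) >= 4))
  expect_identical(f, scads:::make_folds(23, 5, seed = 3))
  expect_error(scads:::make_folds(10, 1, seed = 1), "between 2")
  expect_error(scads:::make_folds(10, 11, seed = 1), "between 2")
})

test_that("noiseless low-rank data are predicted almost perfectly", {
  mb <- make_lowrank(I = 40, block_sizes = c(6, 6), Q = 3, noise = 0,
                     seed = 51)
  cv <- eigenvector_cv(mb, Q = 3, n_folds = 5, seed = 2)
  expect_lt(cv$mpress, 1e-6)
  expect_gte(cv$se, 0)
  expect_true(all(cv$fold_mpress >= 0))
})

test_that("held-out predictions never use the cell they predict", {
  set.seed(52)
  P <- random_orthonormal(8, 3)
  Xh <- matrix(rnorm(4 * 8), 4, 8)
  base <- scads:::ev_predict(P, Xh)
  Xp <- Xh
  Xp[2, 5] <- Xp[2, 5] + 50
  pert <- scads:::ev_predict(P, Xp)
  # the (2,5) prediction itself is unchanged ...
  expect_equal(pert[2, 5], base[2, 5])
  # ... and other rows are completely untouched
  expect_identical(pert[-2, ], base[-2, ])
  # same property for the weight-based scoring rule
  W <- matrix(rnorm(24), 8, 3)
  bw <- scads:::ev_predict_w(W, P, Xh)
  pw <- scads:::ev_predict_w(W, P, Xp)
  expect_equal(pw[2, 5], bw[2, 5])
  expect_identical(pw[-2, ], bw[-2, ])
})

test_that("a changed held-out cell leaves other rows' CV errors intact", {
  mb <- make_lowrank(I = 24, block_sizes = c(5, 5), Q = 2, noise = 0.3,
                     seed = 53)
  cv1 <- eigenvector_cv(mb, Q = 2, n_folds = 4, seed = 7,
                        return_errors = TRUE)
  X2 <- mb$values
  X2[3, 4] <- X2[3, 4] + 10
  mb2 <- multiblock(X2, mb$blocks$size)
  cv2 <- eigenvector_cv(mb2, Q = 2, n_folds = 4, seed = 7,
                        return_errors = TRUE)
  f3 <- cv1$folds[3]
  same_fold <- which(cv1$folds == f3)
  # held-out rows sharing row 3's fold are predicted from a fit that never
  # saw row 3 and from their own values only: their errors are untouched
  # (rows in other folds train on row 3, so they may legitimately change)
  others_in_fold <- setdiff(same_fold, 3)
  expect_identical(cv2$errors[others_in_fold, ],
                   cv1$errors[others_in_fold, ])
  # row 3's own prediction of cell (3,4) did not use the perturbed value:
  # the new residual is exactly (old signed residual + 10)
  r1 <- sqrt(cv1$errors[3, 4]); r2 <- sqrt(cv2$errors[3, 4])
  expect_true(any(abs(r2 - abs(10 + c(-1, 1) * r1)) < 1e-8))
})

test_that("the one-standard-error rule picks the simplest near-optimal model", {
  tab <- data.frame(label = c("a", "b", "c"),
                    mpress = c(0.90, 0.95, 1.20),
                    se = c(0.10, 0.08, 0.30),
                    complexity = c(3, 2, 1))
  sel <- one_se_rule(tab)
  expect_equal(as.integer(sel), 2L)       # within 1.00, simpler than a
  expect_identical(attr(sel, "label"), "b")

  single <- tab[1, ]
  expect_equal(as.integer(one_se_rule(single)), 1L)

  ties <- data.frame(label = c("x", "y", "z"), mpress = c(1, 1, 1),
                     se = c(0.1, 0.1, 0.1), complexity = c(2, 1, 1))
  # equal complexity ties broken by mpress then label order
  expect_identical(attr(one_se_rule(ties), "label"), "y")
  # never returns a candidate above best + best_se
  tab2 <- data.frame(label = letters[1:4], mpress = c(1, 1.05, 1.2, 2),
                     se = c(0.1, 0.1, 0.1, 0.1), complexity = 4:1)
  sel2 <- one_se_rule(tab2)
  expect_lte(tab2$mpress[sel2], tab2$mpress[1] + tab2$se[1])
})

test_that("the number of components is selected around the true rank", {
  mb <- make_lowrank(I = 40, block_sizes = c(8, 8), Q = 3, noise = 0,
                     seed = 54)
  Q <- select_n_components(mb, Q_max = 6, n_folds = 5, seed = 4)
  expect_equal(as.integer(Q), 3L)
  tab <- attr(Q, "table")
  expect_equal(nrow(tab), 6L)
  # the one-SE pick never exceeds the minimum-MPRESS pick
  expect_lte(as.integer(Q), which.min(tab$mpress))
  expect_equal(as.integer(select_n_components(mb, 1, n_folds = 5,
                                              seed = 4)), 1L)
})

test_that("structure search evaluates every candidate on shared folds", {
  sim <- generate_multiblock(60, c(6, 6), "D1 D2 C", c(0.2, 0.2, 0.6),
                             noise_fraction = 0.1, seed = 55)
  sel <- select_structure(sim$data, Q = 3, n_folds = 5, seed = 6)
  tab <- attr(sel, "table")
  expect_s3_class(sel, "scads_structure")
  expect_equal(nrow(tab), count_structures(2, 3))
  expect_false(anyDuplicated(tab$label) > 0)
  expect_true(all(tab$se >= 0))
  expect_true(attr(sel, "best") %in% tab$label)
  # single-block data admit exactly one (all-common) structure, no CV
  one <- select_structure(multiblock(matrix(rnorm(80), 20, 4), 4), Q = 2)
  expect_identical(structure_label(one), "C C")
})

test_that("penalty tuning follows the largest-within-one-SE convention", {
  mb <- make_lowrank(I = 30, block_sizes = c(5, 5), Q = 2, noise = 0.2,
                     seed = 56)
  single <- tune_lambda(mb, Q = 2, grid = 0, which = "lasso", n_folds = 4,
                        seed = 2)
  expect_equal(as.numeric(single), 0)

  # pure noise: the sparsest (largest-penalty) candidate wins
  set.seed(57)
  noise <- multiblock(matrix(rnorm(30 * 10), 30, 10), c(5, 5))
  lmax <- scads:::lambda_max(noise$values, 2, matrix(1, 10, 2))
  sel <- tune_lambda(noise, Q = 2, grid = seq(0, lmax, length.out = 5),
                     which = "lasso", n_folds = 4, seed = 2)
  expect_equal(as.numeric(sel), lmax)
  tab <- attr(sel, "table")
  # the selected penalty is never below the minimum-MPRESS one
  expect_gte(as.numeric(sel), as.numeric(tab$label[which.min(tab$mpress)]))
})

test_that("sequential selection is deterministic and finds planted structure", {
  sim <- generate_multiblock(80, c(6, 6), "D1 D2 C", c(0.2, 0.2, 0.6),
                             noise_fraction = 0.05, seed = 58)
  a <- sequential_select(sim$data, Q_max = 5, n_folds = 5, seed = 10,
                         lasso_grid_size = 5)
  b <- sequential_select(sim$data, Q_max = 5, n_folds = 5, seed = 10,
                         lasso_grid_size = 5)
  expect_identical(a$Q, b$Q)
  expect_identical(structure_label(a$structure),
                   structure_label(b$structure))
  expect_identical(a$lambda1, b$lambda1)
  expect_identical(a$model$W, b$model$W)
  expect_equal(a$Q, 3L)
  # with more units than variables the ridge is dropped
  expect_equal(a$lambda2, 0)
  expect_s3_class(a$model, "scads")
})
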