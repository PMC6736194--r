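test_that("generation is reproducible bit for bit", {
  a <- generate_multiblock(30, c(8, 8), "D1 D2 C", c(0.2, 0.2, 0.6),
                           noise_fraction = 0.25, seed = 41)
  b <- generate_multiblock(30, c(8, 8), "D1 D2 C", c(0.2, 0.2, 0.6),
                           noise_fraction = 0.25, seed = 41)
  expect_identical(a$data$values, b$data$values)
  expect_identical(a$W_true, b$W_true)
  c_ <- generate_multiblock(30, c(8, 8), "D1 D2 C", c(0.2, 0.2, 0.6),
                            noise_fraction = 0.25, seed = 42)
  expect_false(identical(a$data$values, c_$data$values))
})

test_that("the realized noise fraction is exact", {
  for (nf in c(0.05, 0.25, 0.5)) {
    sim <- generate_multiblock(40, c(10, 10), "D1 D2 C",
                               c(0.2, 0.2, 0.6), noise_fraction = nf,
                               seed = 43)
    E <- sim$data$values - sim$X_signal
    expect_lt(abs(sum(E^2) / sum(sim$data$values^2) - nf), 1e-6)
  }
  # noiseless data satisfy the model identity exactly
  s0 <- generate_multiblock(40, c(10, 10), "D1 D2 C", c(0.2, 0.2, 0.6),
                            noise_fraction = 0, seed = 44)
  expect_equal(s0$data$values, s0$X_signal, ignore_attr = TRUE,
               tolerance = 0)
  expect_lt(max(abs(s0$X_signal %*% s0$W_true - s0$T_true)), 1e-9)
})

test_that("zero patterns honor the template and the requested fractions", {
  sim <- generate_multiblock(50, c(10, 10), "D1 D2 C", c(0.2, 0.2, 0.6),
                             noise_fraction = 0.1, seed = 45)
  mask <- structure_mask(sim$template, c(10, 10))
  # template zeros are exact zeros
  expect_true(all(sim$W_true[mask == 0] == 0))
  expect_true(all(sim$P_true[mask == 0] == 0))
  # floor(fraction x free cells) extra zeros per component
  free <- colSums(mask)
  expected_zeros <- (ncol(sim$data$values) - free) +
    floor(c(0.2, 0.2, 0.6) * free)
  expect_equal(unname(colSums(sim$W_true == 0)), unname(expected_zeros))
  # overall 60% zeros per component, the high-sparsity design
  expect_equal(unname(colSums(sim$W_true == 0) / 20), c(0.6, 0.6, 0.6))
  # every participating block keeps at least one nonzero
  for (q in 1:3)
    for (k in unclass(sim$template)[[q]]) {
      cols <- block_columns(sim$data)[[k]]
      expect_gt(sum(sim$W_true[cols, q] != 0), 0)
    }
  # loadings are orthonormal within the pattern
  expect_lt(max(abs(crossprod(sim$P_true) - diag(3))), 1e-10)
})

test_that("infeasible sparsity is rejected", {
  expect_error(generate_multiblock(30, c(4, 4), "D1 D2 C",
                                   c(0.9, 0.9, 0.9), 0.1, seed = 46),
               "sparsity")
  expect_error(generate_multiblock(30, c(4, 4), "D1 D2 C",
                                   c(0.2, 0.2, 0.2), 1.0, seed = 46),
               "noise_fraction")
})

test_that("the crossed simulation designs are as specified", {
  for (setting in c("high_dim", "low_dim")) {
    cond <- simulation_conditions(setting)
    expect_length(cond, 6)
    expect_true(all(vapply(cond, `[[`, 0L, "replications") == 20L))
    expect_setequal(vapply(cond, `[[`, 0, "noise_fraction"),
                    c(0.05, 0.25, 0.5))
    expect_true(all(vapply(cond, `[[`, "", "template") == "D1 D2 C"))
    I <- unique(vapply(cond, `[[`, 0L, "I"))
    bs <- unique(lapply(cond, `[[`, "block_sizes"))
    if (setting == "high_dim") {
      expect_equal(I, 100L)
      expect_equal(bs[[1]], c(250L, 250L))
    } else {
      expect_equal(I, 195L)
      expect_equal(bs[[1]], c(10L, 10L))
    }
  }
  cond <- simulation_conditions("high_dim")
  sp <- vapply(cond, `[[`, "", "sparsity_level")
  # high sparsity: 60% zeros overall in every component
  # -> 0.2 of the distinctive components' free cells, 0.6 of the common
  expect_equal(cond[[which(sp == "high")[1]]]$sparsity, c(0.2, 0.2, 0.6))
  # low sparsity: 52% overall in distinctive (mostly the constrained
  # half), 2% in the common component
  expect_equal(cond[[which(sp == "low")[1]]]$sparsity, c(0.04, 0.04, 0.02))
})

test_that("synthetic datasets round-trip through the sidecar files", {
  sim <- generate_multiblock(20, c(5, 5), "D1 D2 C", c(0.2, 0.2, 0.6),
                             noise_fraction = 0.05, seed = 47)
  d <- tempfile()
  write_synthetic(sim, d)
  back <- read_blocks(file.path(d, paste0(sim$data$blocks$name, ".csv")))
  expect_equal(unname(back$values), unname(sim$data$values))
  Wt <- as.matrix(read.csv(file.path(d, "W_true.csv"), row.names = 1))
  expect_equal(unname(Wt), unname(sim$W_true), tolerance = 1e-12)
})
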