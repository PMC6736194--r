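# Shared fixtures, all generated in code.

# small multiblock with exact low-rank structure plus optional noise
make_lowrank <- function(I = 40, block_sizes = c(6, 6), Q = 3,
                         noise = 0, seed = 1) {
  set.seed(seed)
  J <- sum(block_sizes)
  Tm <- qr.Q(qr(matrix(rnorm(I * Q), I, Q)))
  P <- qr.Q(qr(matrix(rnorm(J * Q), J, Q)))
  X <- Tm %*% t(P)
  if (noise > 0) X <- X + noise * matrix(rnorm(I * J), I, J)
  multiblock(X, block_sizes = block_sizes)
}

random_orthonormal <- function(J, Q) {
  qr.Q(qr(matrix(rnorm(J * Q), J, Q)))
}

# brute-force structure enumeration: all Q-tuples of nonempty subsets,
# canonicalized (sorted labels) and deduplicated
brute_force_structures <- function(K, Q) {
  subsets <- unlist(lapply(seq_len(K), function(size)
    utils::combn(K, size, simplify = FALSE)), recursive = FALSE)
  keys <- vapply(subsets, function(s)
    paste0(length(s), ":", paste(s, collapse = ",")), "")
  grids <- do.call(expand.grid, rep(list(seq_along(subsets)), Q))
  canon <- apply(grids, 1L, function(idx)
    paste(sort(keys[idx]), collapse = " | "))
  unique(canon)
}

# objective evaluated by direct elementwise arithmetic (independent of the
# package's linear-algebra shortcuts)
brute_objective <- function(X, W, P, lambda1, lambda2) {
  R <- X - X %*% W %*% t(P)
  sum(R * R) + lambda1 * sum(abs(W)) + lambda2 * sum(W * W)
}
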