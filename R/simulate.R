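#' Generate multi-block data under a sparse SCA model
#'
#' Draws a low-rank signal with a known common/distinctive sparse weight
#' structure plus homoscedastic Gaussian noise at an exactly controlled
#' fraction of the total variation. Construction: (1) loadings `P_true`
#' with the template's zero blocks, random-signed magnitudes on free cells,
#' extra zeros placed uniformly to hit each component's zero fraction, then
#' orthonormalized within the zero pattern by alternating projections;
#' (2) orthonormalized standard-normal scores `T_true`; (3) signal
#' `X_signal = T_true P_true'` and `W_true` the minimum-norm matrix with
#' the same zero pattern solving `X_signal W_true = T_true`; (4) noise made
#' orthogonal to the signal (Frobenius inner product) and rescaled so the
#' realized noise fraction `||E||^2 / ||X||^2` equals `noise_fraction`
#' exactly.
#'
#' @param I number of observation units.
#' @param block_sizes integer vector of block sizes.
#' @param template a [structure_template] or label such as `"D1 D2 C"`.
#' @param sparsity per-component zero fraction of the component's *free*
#'   cells (vector of length Q, in the template's canonical component
#'   order). The number of extra zeros is `floor(sparsity * free cells)`;
#'   each block participating in a component keeps at least one nonzero.
#' @param noise_fraction fraction of total variation due to noise, in
#'   `[0, 1)`.
#' @param seed integer seed; identical seeds give bit-identical datasets.
#' @param max_retries orthonormalization retries (fresh substream) before
#'   giving up under extreme sparsity.
#' @return an object of class `"scads_sim"`: list with `data` (a
#'   [multiblock]), `W_true`, `P_true`, `T_true`, `X_signal`,
#'   `noise_fraction`, `template`, `sparsity`, `seed`.
#' @export
generate_multiblock <- function(I, block_sizes, template, sparsity,
                                noise_fraction, seed,
                                max_retries = 10L) {
  block_sizes <- as.integer(block_sizes)
  K <- length(block_sizes)
  if (is.character(template)) template <- parse_structure(template, K)
  Q <- length(template)
  sparsity <- rep_len(as.numeric(sparsity), Q)
  if (any(sparsity < 0 | sparsity >= 1))
    stop("sparsity fractions must be in [0, 1)")
  if (noise_fraction < 0 || noise_fraction >= 1)
    stop("noise_fraction must be in [0, 1)")
  mask <- structure_mask(template, block_sizes)
  J <- sum(block_sizes)
  if (I <= Q || J <= Q) stop("need I > Q and J > Q")

  for (attempt in seq_len(max_retries)) {
    set.seed(as.integer(seed) + (attempt - 1L) * 104729L)
    P <- draw_sparse_loadings(mask, sparsity, template, block_sizes)
    P <- orthonormalize_in_pattern(P)
    if (is.null(P)) next
    pattern <- P != 0

    Tm <- qr.Q(qr(matrix(stats::rnorm(I * Q), I, Q)))
    Xs <- Tm %*% t(P)

    W <- min_norm_weights(Xs, Tm, pattern)
    if (is.null(W)) next

    E <- matrix(stats::rnorm(I * J), I, J)
    E <- E - (sum(E * Xs) / sum(Xs^2)) * Xs  # exact noise fraction below
    X <- Xs
    if (noise_fraction > 0) {
      cfac <- sqrt(noise_fraction / (1 - noise_fraction) *
                     sum(Xs^2) / sum(E^2))
      X <- Xs + cfac * E
    }
    data <- multiblock(X, block_sizes = block_sizes)
    return(structure(list(
      data = data, W_true = W, P_true = P, T_true = Tm, X_signal = Xs,
      noise_fraction = noise_fraction, template = template,
      sparsity = sparsity, seed = seed
    ), class = "scads_sim"))
  }
  stop("could not generate an orthonormal sparse loading pattern after ",
       max_retries, " attempts; relax the sparsity")
}

#' @export
print.scads_sim <- function(x, ...) {
  cat("Synthetic multi-block dataset (seed ", x$seed, ")\n", sep = "")
  cat("  structure: ", structure_label(x$template), "\n", sep = "")
  cat(sprintf("  %d x %d, noise fraction %.3g, zeros per component: %s\n",
              x$data$I, x$data$J, x$noise_fraction,
              paste(colSums(x$W_true == 0), collapse = ", ")))
  invisible(x)
}

## free cells get sign * U(0.5, 1.5); extra zeros uniform over free cells,
## reserving one nonzero per participating block
draw_sparse_loadings <- function(mask, sparsity, template, block_sizes) {
  J <- nrow(mask); Q <- ncol(mask)
  ends <- cumsum(block_sizes); starts <- ends - block_sizes + 1L
  P <- matrix(0, J, Q)
  for (q in seq_len(Q)) {
    free <- which(mask[, q] == 1)
    vals <- sample(c(-1, 1), length(free), replace = TRUE) *
      stats::runif(length(free), 0.5, 1.5)
    P[free, q] <- vals
    n_zero <- floor(sparsity[q] * length(free))
    if (n_zero > 0L) {
      blocks <- unclass(template)[[q]]
      keep <- vapply(blocks, function(k) {
        in_blk <- intersect(free, starts[k]:ends[k])
        in_blk[sample.int(length(in_blk), 1L)]
      }, 0L)
      eligible <- setdiff(free, keep)
      if (n_zero > length(eligible))
        stop("sparsity incompatible with the template: component ", q,
             " cannot keep one nonzero per block")
      z <- eligible[sample.int(length(eligible), n_zero)]
      P[z, q] <- 0
    }
  }
  P
}

## alternating projections between the Stiefel manifold (polar
## orthonormalization) and the zero pattern; NULL on failure
orthonormalize_in_pattern <- function(P, tol = 1e-12, max_iter = 500L) {
  pattern <- P != 0
  for (it in seq_len(max_iter)) {
    sv <- svd(P)
    if (min(sv$d) < 1e-10) return(NULL)
    P <- sv$u %*% t(sv$v)            # nearest column-orthonormal matrix
    P[!pattern] <- 0
    nrm <- sqrt(colSums(P^2))
    if (any(nrm < 1e-8)) return(NULL)
    P <- sweep(P, 2L, nrm, "/")
    Q <- ncol(P)
    if (max(abs(crossprod(P) - diag(Q))) < tol) return(P)
  }
  NULL
}

## per component: minimum-norm w on the support solving X w = t_q
min_norm_weights <- function(Xs, Tm, pattern) {
  J <- ncol(Xs); Q <- ncol(Tm)
  W <- matrix(0, J, Q)
  for (q in seq_len(Q)) {
    S <- which(pattern[, q])
    sv <- svd(Xs[, S, drop = FALSE])
    pos <- sv$d > max(sv$d) * 1e-10
    w <- sv$v[, pos, drop = FALSE] %*%
      ((crossprod(sv$u[, pos, drop = FALSE], Tm[, q])) / sv$d[pos])
    if (max(abs(Xs[, S, drop = FALSE] %*% w - Tm[, q])) > 1e-8)
      return(NULL)                   # score not reachable on this support
    W[S, q] <- w
  }
  W
}

#' Crossed simulation-design conditions
#'
#' The six conditions of the recovery and structure-selection studies: a
#' fully crossed design of noise fraction (5, 25, 50 percent of total
#' variation) by weight sparsity (high: 60 percent zeros in every
#' component; low: 2 percent zeros in the common component and 52 percent
#' in the distinctive components), with true structure `"D1 D2 C"` over two
#' equal blocks and 20 replications per condition. The high-dimensional
#' setting uses 100 units and two blocks of 250 variables; the
#' low-dimensional one 195 units and two blocks of 10.
#'
#' Sparsity in each descriptor is expressed as the zero fraction of each
#' component's *free* cells (what [generate_multiblock()] consumes),
#' converted from the overall per-component zero percentages above.
#'
#' @param setting `"high_dim"` or `"low_dim"`.
#' @return list of six condition descriptors (lists with `name`,
#'   `sparsity_level`, `noise_fraction`, `I`, `block_sizes`, `template`,
#'   `sparsity`, `replications`).
#' @export
simulation_conditions <- function(setting = c("high_dim", "low_dim")) {
  setting <- match.arg(setting)
  I <- if (setting == "high_dim") 100L else 195L
  bs <- if (setting == "high_dim") c(250L, 250L) else c(10L, 10L)
  template <- "D1 D2 C"
  overall <- list(high = c(0.60, 0.60, 0.60),  # D1, D2, C overall zeros
                  low  = c(0.52, 0.52, 0.02))
  out <- list()
  for (sp in c("high", "low")) {
    free_frac <- overall_to_free_fraction(template, bs, overall[[sp]])
    for (nf in c(0.05, 0.25, 0.50)) {
      out[[length(out) + 1L]] <- list(
        name = sprintf("%s sparsity, %d%% noise", sp, round(100 * nf)),
        sparsity_level = sp, noise_fraction = nf, I = I,
        block_sizes = bs, template = template, sparsity = free_frac,
        replications = 20L)
    }
  }
  out
}

## overall zero fraction of a component (over all J cells) -> zero fraction
## of its free cells, given the template's constrained zeros
overall_to_free_fraction <- function(template, block_sizes, overall) {
  if (is.character(template))
    template <- parse_structure(template, length(block_sizes))
  J <- sum(block_sizes)
  vapply(seq_along(unclass(template)), function(q) {
    s <- unclass(template)[[q]]
    free <- sum(block_sizes[s])
    constrained <- J - free
    max(0, (overall[q] * J - constrained) / free)
  }, 0)
}

#' Write a synthetic dataset with its ground truth
#'
#' Data blocks as CSVs (via [write_blocks()]) plus `W_true.csv`,
#' `P_true.csv`, and a `truth.json` sidecar with the template, sparsity,
#' noise fraction and seed, so simulations can be replayed.
#'
#' @param sim a [generate_multiblock()] result.
#' @param dir output directory.
#' @return invisibly, `dir`.
#' @export
write_synthetic <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_blocks(sim$data, dir)
  utils::write.csv(sim$W_true, file.path(dir, "W_true.csv"))
  utils::write.csv(sim$P_true, file.path(dir, "P_true.csv"))
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    jsonlite::write_json(
      list(template = structure_label(sim$template),
           sparsity = sim$sparsity,
           noise_fraction = sim$noise_fraction, seed = sim$seed),
      file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}
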