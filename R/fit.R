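#' Sparse common and distinctive simultaneous component analysis
#'
#' Fits the penalized simultaneous component model on concatenated
#' multi-block data: find a J x Q weight matrix W and a column-orthonormal
#' J x Q loading matrix P minimizing
#' \deqn{\|X - X W P^\top\|_F^2 + \lambda_1 \|W\|_1 + \lambda_2 \|W\|_F^2}
#' subject to W being zero outside the constraint mask implied by the
#' common/distinctive `structure`. Component scores are `T = X W`, so
#' sparsity in W directly selects the variables a component is built from.
#'
#' Estimation alternates an analytic loadings update (reduced-rank
#' Procrustes via the singular value decomposition of `X'XW`) with a
#' coordinate-descent weights update (exact univariate soft-threshold
#' minimizers, masked cells never touched), which yields a non-increasing
#' sequence of loss values. With `lambda1 = 0` the weights update is solved
#' exactly per component as a (ridge) least-squares problem. With
#' `lambda1 = lambda2 = 0` and an all-common structure the model is
#' ordinary PCA/SCA of the concatenated data.
#'
#' @param data a [multiblock] object or numeric matrix (I x J), already
#'   preprocessed (see [center_scale()], [block_scale()]).
#' @param Q number of components; defaults to the number of components of
#'   `structure` when that is given.
#' @param structure a [structure_template], a label such as `"D1 D2 C"`, or
#'   `NULL` for the unconstrained (all-common) model.
#' @param lambda1 lasso penalty weight, a scalar or per-component vector of
#'   length Q; >= 0.
#' @param lambda2 ridge penalty weight (scalar, >= 0).
#' @param n_starts number of starts: start 1 is the deterministic SVD-based
#'   start, further starts draw standard-normal free weights.
#' @param tol convergence tolerance on the relative decrease of the loss.
#' @param max_iter maximum number of alternating iterations per start.
#' @param seed optional integer seed for the random starts.
#' @param mask optional explicit J x Q binary constraint mask, overriding
#'   `structure`.
#' @return an object of class `"scads"` with elements `W` (weights, exactly
#'   zero where masked), `P` (loadings, orthonormal columns), `scores`
#'   (`T = X W`), `lambda1`, `lambda2`, `mask`, `structure`, `loss` (trace
#'   of loss values of the winning start), `objective`, `converged`,
#'   `iterations`, `start` (index of the winning start), `empty_components`
#'   (components whose weights were thresholded to all-zero), and `vaf`
#'   (percent variance accounted for, total and per component).
#' @seealso [sparse_pca()], [tune_lasso_cardinality()], [eigenvector_cv()]
#' @examples
#' set.seed(1)
#' sim <- generate_multiblock(I = 50, block_sizes = c(10, 10),
#'                            template = "D1 D2 C",
#'                            sparsity = c(0.2, 0.2, 0.6),
#'                            noise_fraction = 0.05, seed = 7)
#' fit <- scads(sim$data, structure = "D1 D2 C", lambda1 = 1e-4)
#' fit
#' @export
scads <- function(data, Q = NULL, structure = NULL, lambda1 = 0,
                  lambda2 = 0, n_starts = 1L, tol = 1e-8, max_iter = 500L,
                  seed = NULL, mask = NULL) {
  mb <- as_multiblock(data)
  X <- mb$values
  if (is.character(structure)) structure <- parse_structure(structure, mb$K)
  if (is.null(mask)) {
    if (!is.null(structure)) {
      mask <- structure_mask(structure, mb)
      if (is.null(Q)) Q <- length(structure)
      if (Q != length(structure))
        stop("Q disagrees with the number of components in `structure`")
    } else {
      if (is.null(Q)) stop("supply Q, a structure, or a mask")
      mask <- matrix(1, ncol(X), Q)
    }
  } else {
    mask <- (as.matrix(mask) != 0) * 1
    if (is.null(Q)) Q <- ncol(mask)
  }
  fit <- scads_core(X, Q = Q, mask = mask, lambda1 = lambda1,
                    lambda2 = lambda2, n_starts = n_starts, tol = tol,
                    max_iter = max_iter, seed = seed)
  fit$structure <- structure
  fit$blocks <- mb$blocks
  dimnames(fit$W) <- dimnames(fit$P) <-
    list(colnames(X), paste0("comp", seq_len(Q)))
  fit$scores <- X %*% fit$W
  fit$vaf <- vaf_from_parts(X, fit$W, fit$P)
  fit$call <- match.call()
  fit
}

#' Sparse PCA of the concatenated data
#'
#' The unconstrained special case of [scads()]: an all-ones mask, i.e. no
#' common/distinctive zero blocks. This is the baseline analysis that
#' ignores the multi-block structure.
#'
#' @inheritParams scads
#' @return a `"scads"` object, identical field-for-field to
#'   `scads(data, Q, mask = all-ones, ...)` under the same seed.
#' @export
sparse_pca <- function(data, Q, lambda1 = 0, lambda2 = 0, n_starts = 1L,
                       tol = 1e-8, max_iter = 500L, seed = NULL) {
  mb <- as_multiblock(data)
  out <- scads(mb, Q = Q, structure = NULL, lambda1 = lambda1,
               lambda2 = lambda2, n_starts = n_starts, tol = tol,
               max_iter = max_iter, seed = seed)
  out$call <- match.call()
  out
}

## Core fitting routine on a bare matrix. XtX may be precomputed and is
## only formed for the coordinate-descent path (lambda1 > 0).
scads_core <- function(X, Q, mask, lambda1, lambda2, n_starts = 1L,
                       tol = 1e-8, max_iter = 500L, seed = NULL,
                       XtX = NULL, W_init = NULL) {
  I <- nrow(X); J <- ncol(X)
  if (Q > min(I, J)) stop("Q must not exceed min(I, J)")
  stopifnot(nrow(mask) == J, ncol(mask) == Q)
  lambda1 <- rep_len(as.numeric(lambda1), Q)
  if (any(lambda1 < 0) || lambda2 < 0) stop("penalties must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  ssqX <- sum(X^2)
  use_cd <- any(lambda1 > 0)
  if (use_cd && is.null(XtX)) XtX <- crossprod(X)

  starts <- vector("list", n_starts)
  W_svd <- svd_start(X, Q, mask)
  for (s in seq_len(n_starts)) {
    W0 <- if (s == 1L) {
      if (!is.null(W_init)) W_init * mask else W_svd
    } else random_start(J, Q, mask)
    res <- if (use_cd) {
      .scads_cd_fit_cpp(XtX, ssqX, W0, mask, lambda1, lambda2, tol,
                        as.integer(max_iter))
    } else {
      .scads_exact_fit_cpp(X, ssqX, W0, mask, lambda2, tol,
                           as.integer(max_iter))
    }
    res$start <- s
    starts[[s]] <- res
  }
  objs <- vapply(starts, function(r) r$trace[length(r$trace)], 0)
  best <- starts[[which.min(objs)]]
  sgn <- sign_convention(best$W, best$P)
  structure(list(
    W = sgn$W, P = sgn$P,
    lambda1 = lambda1, lambda2 = lambda2, mask = mask,
    loss = best$trace, objective = unname(objs[which.min(objs)]),
    converged = isTRUE(best$converged),
    iterations = best$iterations, start = best$start,
    n_starts = n_starts,
    empty_components = colSums(abs(sgn$W)) == 0,
    I = I, J = J, Q = Q, ssqX = ssqX
  ), class = "scads")
}

## Deterministic start: leading-Q right singular vectors, masked and
## renormalized per column; degenerate columns fall back to random draws.
svd_start <- function(X, Q, mask) {
  V <- svd(X, nu = 0L, nv = Q)$v
  W0 <- V * mask
  for (q in seq_len(Q)) {
    nrm <- sqrt(sum(W0[, q]^2))
    if (nrm < 1e-12) {
      free <- which(mask[, q] == 1)
      W0[free, q] <- stats::rnorm(length(free))
      nrm <- sqrt(sum(W0[, q]^2))
    }
    W0[, q] <- W0[, q] / nrm
  }
  W0
}

random_start <- function(J, Q, mask) {
  W0 <- matrix(0, J, Q)
  free <- mask == 1
  W0[free] <- stats::rnorm(sum(free))
  W0
}

## Remove the sign indeterminacy: flip (w_q, p_q) jointly so the
## largest-magnitude weight (or loading, for empty components) is positive.
sign_convention <- function(W, P) {
  for (q in seq_len(ncol(W))) {
    ref <- if (any(W[, q] != 0)) W[which.max(abs(W[, q])), q]
           else P[which.max(abs(P[, q])), q]
    if (!is.na(ref) && ref < 0) {
      W[, q] <- -W[, q]
      P[, q] <- -P[, q]
    }
  }
  list(W = W, P = P)
}

#' Value of the penalized SCaDS criterion
#'
#' \eqn{\|X - XWP^\top\|_F^2 + \lambda_1\|W\|_1 + \lambda_2\|W\|_F^2};
#' the penalties act on the weights only, never on the loadings.
#'
#' @param X numeric I x J matrix.
#' @param W J x Q weight matrix.
#' @param P J x Q loading matrix.
#' @param lambda1 lasso weight, scalar or per-component vector.
#' @param lambda2 ridge weight.
#' @return a nonnegative scalar.
#' @export
scads_objective <- function(X, W, P, lambda1 = 0, lambda2 = 0) {
  if (ncol(X) != nrow(W) || !all(dim(W) == dim(P)))
    stop("dimension mismatch")
  lambda1 <- rep_len(as.numeric(lambda1), ncol(W))
  sum((X - X %*% W %*% t(P))^2) +
    sum(lambda1 * colSums(abs(W))) + lambda2 * sum(W^2)
}

#' Analytic loadings update (reduced-rank Procrustes)
#'
#' For fixed weights the column-orthonormal P minimizing
#' \eqn{\|X - XWP^\top\|_F^2} is \eqn{UV^\top} from the thin singular value
#' decomposition \eqn{X^\top X W = U D V^\top}. Rank deficiencies are
#' resolved deterministically by the LAPACK decomposition.
#'
#' @inheritParams scads_objective
#' @return J x Q matrix with orthonormal columns.
#' @export
update_loadings <- function(X, W) {
  if (sum(abs(W)) == 0) stop("no active components")
  M <- crossprod(X, X %*% W)
  Q <- ncol(W)
  sv <- svd(M, nu = Q, nv = Q)
  sv$u %*% t(sv$v)
}

#' One coordinate-descent sweep over the free weights
#'
#' Sweeps all free (mask = 1) cells once, components in order and variables
#' in natural order, setting each weight to the exact minimizer of the
#' criterion as a univariate function: a soft-threshold at
#' \eqn{\lambda_1/2} divided by \eqn{(X^\top X)_{jj} + \lambda_2}.
#' Masked cells are never updated.
#'
#' @inheritParams scads_objective
#' @param mask J x Q binary matrix of free cells.
#' @param W_current current weights (masked cells must be zero).
#' @return updated J x Q weight matrix.
#' @export
update_weights <- function(X, P, lambda1, lambda2, mask, W_current) {
  Q <- ncol(P)
  if (max(abs(crossprod(P) - diag(Q))) > 1e-6)
    stop("P must have orthonormal columns")
  XtX <- crossprod(X)
  .cd_sweep_cpp(XtX, XtX %*% P, W_current, (mask != 0) * 1,
                rep_len(as.numeric(lambda1), Q), lambda2)
}

## Smallest lambda1 at which a full sweep from W = 0 leaves everything at
## zero: 2 * max |(X'X P0)_jq| over free cells, P0 from the SVD start.
lambda_max <- function(X, Q, mask, XtX = NULL) {
  if (is.null(XtX)) XtX <- crossprod(X)
  W0 <- svd_start(X, Q, mask)
  M <- XtX %*% W0
  sv <- svd(M, nu = Q, nv = Q)
  P0 <- sv$u %*% t(sv$v)
  2 * max(abs((XtX %*% P0)[mask == 1]))
}

#' Tune the lasso to a target number of nonzero weights
#'
#' Bisection on \eqn{\lambda_1} over \eqn{[0, \lambda_{max}]} until the
#' fitted model has the requested number of nonzero weights (within
#' `tol_fraction` of the target), mirroring cardinality-matched tuning in
#' recovery experiments. With `per_component = TRUE`, `target_nonzeros` is
#' a per-component vector and a per-component \eqn{\lambda_1} vector is
#' bisected simultaneously.
#'
#' @inheritParams scads
#' @param target_nonzeros requested count of nonzero weights (total, or per
#'   component when `per_component = TRUE`).
#' @param tol_fraction relative tolerance on the achieved count (default
#'   1e-4, i.e. 0.01 percent).
#' @param per_component tune one lasso weight per component.
#' @param max_steps maximum bisection steps.
#' @return list with `lambda1`, the fitted `model`, `achieved` counts,
#'   `target`, and `reached` (`FALSE` means the bracket collapsed on the
#'   nearest achievable count, reported with a warning).
#' @export
tune_lasso_cardinality <- function(data, Q = NULL, structure = NULL,
                                   mask = NULL, lambda2 = 0,
                                   target_nonzeros, tol_fraction = 1e-4,
                                   per_component = FALSE, max_steps = 60L,
                                   tol = 1e-8, max_iter = 500L,
                                   seed = NULL) {
  mb <- as_multiblock(data)
  X <- mb$values
  if (is.character(structure)) structure <- parse_structure(structure, mb$K)
  if (is.null(mask)) {
    if (!is.null(structure)) mask <- structure_mask(structure, mb)
    else mask <- matrix(1, ncol(X), Q)
  }
  mask <- (as.matrix(mask) != 0) * 1
  if (is.null(Q)) Q <- ncol(mask)
  XtX <- crossprod(X)
  lmax <- lambda_max(X, Q, mask, XtX)
  free_tot <- if (per_component) colSums(mask) else sum(mask)
  target <- as.numeric(target_nonzeros)
  if (any(target < 0) || any(target > free_tot))
    stop("target_nonzeros outside [0, number of free cells]")
  tol_n <- pmax(tol_fraction * target, 0)

  count_of <- function(fit) {
    if (per_component) colSums(fit$W != 0) else sum(fit$W != 0)
  }
  fit_at <- function(l1, W_init = NULL)
    scads_core(X, Q, mask, lambda1 = l1, lambda2 = lambda2,
               n_starts = 1L, tol = tol, max_iter = max_iter,
               seed = seed, XtX = XtX, W_init = W_init)

  nl <- if (per_component) Q else 1L
  lo <- rep(0, nl); hi <- rep(lmax, nl)
  reached <- FALSE
  Wwarm <- NULL
  # evaluate the upper bracket first: the all-zero end of the path (a cold
  # W = 0 start there is the definition of lambda_max)
  best <- scads_core(X, Q, mask, lambda1 = if (per_component) hi else hi[1L],
                     lambda2 = lambda2, n_starts = 1L, tol = tol,
                     max_iter = max_iter, seed = seed, XtX = XtX,
                     W_init = matrix(0, ncol(X), Q))
  best_gap <- sum(abs(count_of(best) - target))
  best_l <- hi
  if (all(abs(count_of(best) - target) <= tol_n)) reached <- TRUE
  for (step in if (reached) integer(0) else seq_len(max_steps)) {
    mid <- (lo + hi) / 2
    fit <- fit_at(if (per_component) mid else mid[1L], W_init = Wwarm)
    Wwarm <- fit$W
    cnt <- count_of(fit)
    gap <- sum(abs(cnt - target))
    if (gap < best_gap) {
      best_gap <- gap; best <- fit; best_l <- mid
    }
    if (all(abs(cnt - target) <= tol_n)) { reached <- TRUE; break }
    over <- cnt > target       # too many nonzeros -> raise the penalty
    lo[over] <- mid[over]
    hi[!over] <- mid[!over]
    if (all(hi - lo < 1e-12 * max(lmax, 1))) break
  }
  if (!reached)
    warning("cardinality target not reached exactly; nearest achieved: ",
            paste(count_of(best), collapse = ","))
  list(lambda1 = if (per_component) best_l else best_l[1L],
       model = best, achieved = count_of(best), target = target,
       lambda_max = lmax, reached = reached)
}
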