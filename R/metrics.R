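#' Align estimated components to reference components
#'
#' Component order and sign are not identified, so before comparing an
#' estimated weight matrix with a reference one the estimated columns are
#' permuted (optimal assignment on absolute column-wise congruence) and
#' sign-flipped so every matched column congruence is nonnegative.
#'
#' @param W_ref J x Q reference matrix.
#' @param W_hat J x Q estimated matrix.
#' @return list with `W` (the aligned estimate), `perm` (the permutation
#'   applied to the estimated columns) and `signs`.
#' @export
align_components <- function(W_ref, W_hat) {
  stopifnot(all(dim(W_ref) == dim(W_hat)))
  Q <- ncol(W_ref)
  C <- matrix(0, Q, Q)
  for (a in seq_len(Q))
    for (b in seq_len(Q))
      C[a, b] <- column_congruence(W_ref[, a], W_hat[, b])
  perm <- best_assignment(abs(C))
  signs <- vapply(seq_len(Q), function(a) {
    s <- sign(C[a, perm[a]])
    if (s == 0) 1 else s
  }, 0)
  W <- sweep(W_hat[, perm, drop = FALSE], 2L, signs, "*")
  list(W = W, perm = perm, signs = signs)
}

column_congruence <- function(a, b) {
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) return(0)
  sum(a * b) / (na * nb)
}

## exhaustive assignment; Q is small (components), Q! permutations
best_assignment <- function(score) {
  Q <- nrow(score)
  if (Q == 1L) return(1L)
  if (Q > 8L) {   # greedy fallback for unusually many components
    perm <- integer(Q)
    left <- seq_len(Q)
    for (a in seq_len(Q)) {
      b <- left[which.max(score[a, left])]
      perm[a] <- b
      left <- setdiff(left, b)
    }
    return(perm)
  }
  perms <- permutations_of(Q)
  totals <- vapply(perms, function(p) sum(score[cbind(seq_len(Q), p)]), 0)
  perms[[which.max(totals)]]
}

permutations_of <- function(n) {
  if (n == 1L) return(list(1L))
  sub <- permutations_of(n - 1L)
  out <- list()
  for (p in sub)
    for (pos in seq_len(n))
      out[[length(out) + 1L]] <- append(p, n, after = pos - 1L)
  out
}

#' Tucker's coefficient of congruence on vectorized weight matrices
#'
#' The cosine of the angle between the two matrices after vectorization, a
#' standardized measure of proportionality. Values of 0.85-0.95 indicate
#' fair similarity, above 0.95 near-equal matrices. With `align = TRUE`
#' (the default) the estimated components are first permuted and
#' sign-flipped to best match the reference, removing label switching.
#'
#' @inheritParams align_components
#' @param align permute/sign-align estimated components first.
#' @return a scalar in [-1, 1], with attribute `"band"` giving the
#'   interpretation band (`"near equal"`, `"fair"`, or `"low"`).
#' @export
tucker_congruence <- function(W_ref, W_hat, align = TRUE) {
  stopifnot(all(dim(W_ref) == dim(W_hat)))
  if (sum(W_ref^2) == 0 || sum(W_hat^2) == 0)
    stop("all-zero matrix has no direction")
  if (align) W_hat <- align_components(W_ref, W_hat)$W
  phi <- column_congruence(as.vector(W_ref), as.vector(W_hat))
  band <- if (phi >= 0.95) "near equal" else if (phi >= 0.85) "fair" else "low"
  structure(phi, band = band)
}

#' Percentage of correctly classified zero/nonzero weights
#'
#' A cell counts as correctly classified when it is nonzero in both the
#' reference and the estimate or zero in both. Reference zeros are exact;
#' estimated magnitudes below `tol` count as zero (coordinate descent
#' produces exact zeros, so any tolerance below the smallest true magnitude
#' is equivalent).
#'
#' @inheritParams tucker_congruence
#' @param tol magnitude below which an estimated weight counts as zero.
#' @return a percentage in [0, 100].
#' @export
classification_rate <- function(W_ref, W_hat, align = TRUE, tol = 1e-12) {
  stopifnot(all(dim(W_ref) == dim(W_hat)))
  if (align) W_hat <- align_components(W_ref, W_hat)$W
  truth <- W_ref != 0
  est <- abs(W_hat) > tol
  100 * mean(truth == est)
}

#' Percentage of variance accounted for
#'
#' Total: \eqn{100 (1 - \|X - XWP^\top\|_F^2 / \|X\|_F^2)}. Per component:
#' the rank-one reconstruction \eqn{100 \|X w_q p_q^\top\|_F^2/\|X\|_F^2}.
#' Per-component values need not sum to the total when component scores are
#' correlated.
#'
#' @param X the (preprocessed) data the model was fitted on.
#' @param model a fitted [scads()] model.
#' @return list with `total` and `per_component`.
#' @export
vaf <- function(X, model) {
  X <- if (inherits(X, "multiblock")) X$values else as.matrix(X)
  vaf_from_parts(X, model$W, model$P)
}

vaf_from_parts <- function(X, W, P) {
  ssq <- sum(X^2)
  if (ssq == 0) stop("data matrix has zero sum of squares")
  TT <- X %*% W
  total <- 100 * (1 - sum((X - TT %*% t(P))^2) / ssq)
  per <- vapply(seq_len(ncol(W)), function(q)
    100 * sum(TT[, q]^2) * sum(P[, q]^2) / ssq, 0)
  names(per) <- colnames(W)
  list(total = total, per_component = per)
}

#' Recovery report comparing an estimate with the truth
#'
#' @inheritParams tucker_congruence
#' @return list with `tucker`, its interpretation `band`,
#'   `pct_correct_classified`, and the `alignment` used.
#' @export
recovery_report <- function(W_ref, W_hat) {
  al <- align_components(W_ref, W_hat)
  tk <- tucker_congruence(W_ref, al$W, align = FALSE)
  list(tucker = as.numeric(tk), band = attr(tk, "band"),
       pct_correct_classified =
         classification_rate(W_ref, al$W, align = FALSE),
       alignment = al[c("perm", "signs")])
}
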