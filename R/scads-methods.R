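#' @export
print.scads <- function(x, ...) {
  lab <- if (!is.null(x$structure)) structure_label(x$structure)
         else "unconstrained"
  cat("Sparse common/distinctive SCA fit\n")
  cat(sprintf("  %d units, %d variables, %d components (%s)\n",
              x$I, x$J, x$Q, lab))
  cat(sprintf("  lambda1 = %s, lambda2 = %g\n",
              paste(signif(unique(x$lambda1), 4), collapse = "/"),
              x$lambda2))
  cat(sprintf("  nonzero weights: %d of %d free (%d constrained to zero)\n",
              sum(x$W != 0), sum(x$mask == 1), sum(x$mask == 0)))
  cat(sprintf("  loss = %.6g after %d iterations (%s), VAF = %.1f%%\n",
              x$objective, x$iterations,
              if (x$converged) "converged" else "max_iter reached",
              x$vaf$total))
  if (any(x$empty_components))
    cat("  note: component(s)",
        paste(which(x$empty_components), collapse = ", "),
        "lost all weights to the lasso\n")
  invisible(x)
}

#' @export
summary.scads <- function(object, ...) {
  out <- list(
    fit = object,
    nonzero_per_component = colSums(object$W != 0),
    vaf = object$vaf
  )
  class(out) <- "summary.scads"
  out
}

#' @export
print.summary.scads <- function(x, ...) {
  print(x$fit)
  cat("\nNonzero weights per component:\n")
  print(x$nonzero_per_component)
  cat("\n%VAF per component:\n")
  print(round(x$vaf$per_component, 2))
  invisible(x)
}

#' @export
coef.scads <- function(object, type = c("weights", "loadings"), ...) {
  type <- match.arg(type)
  if (type == "weights") object$W else object$P
}

#' Component scores for new observation units
#'
#' `T_new = X_new W`: because the weights are sparse, only variables with a
#' nonzero weight have to be measured to score a new unit. New data must be
#' preprocessed with the training preprocessing parameters.
#'
#' @param object a fitted [scads()] model.
#' @param newdata a [multiblock] object or matrix with the training J
#'   columns; omitted, the training scores are returned.
#' @param ... unused.
#' @return an I_new x Q matrix of component scores.
#' @export
predict.scads <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$scores)
  X <- if (inherits(newdata, "multiblock")) newdata$values
       else as.matrix(newdata)
  if (ncol(X) != nrow(object$W))
    stop("newdata has ", ncol(X), " columns but the model has ",
         nrow(object$W), " variables")
  X %*% object$W
}

#' @export
fitted.scads <- function(object, ...) {
  object$scores %*% t(object$P)
}

#' @export
residuals.scads <- function(object, data, ...) {
  X <- if (inherits(data, "multiblock")) data$values else as.matrix(data)
  X - fitted(object)
}

#' Plot a fitted model
#'
#' `type = "loss"` shows the (non-increasing) loss trace of the winning
#' start; `type = "weights"` an image of absolute component weights with
#' block boundaries.
#'
#' @param x a fitted [scads()] model.
#' @param type what to plot.
#' @param ... passed to the underlying plotting function.
#' @export
plot.scads <- function(x, type = c("loss", "weights"), ...) {
  type <- match.arg(type)
  if (type == "loss") {
    graphics::plot(seq_along(x$loss), x$loss, type = "b", pch = 16,
                   xlab = "alternating half-step", ylab = "loss", ...)
  } else {
    graphics::image(t(abs(x$W))[, rev(seq_len(nrow(x$W))), drop = FALSE],
                    axes = FALSE, xlab = "component", ylab = "variable",
                    ...)
    if (!is.null(x$blocks)) {
      cuts <- 1 - (x$blocks$end[-length(x$blocks$end)] / nrow(x$W))
      graphics::abline(h = cuts, lwd = 2, col = "white")
    }
  }
  invisible(x)
}
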