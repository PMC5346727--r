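#' Construct a regression problem
#'
#' A light container tying a design matrix to its response, per-coefficient
#' lower bounds and column metadata.  Produced by [build_grn_regression()]
#' and [build_ppin_regression()] and consumed by
#' [constrained_least_squares()] and [prune_by_aic()].
#'
#' @param Phi Design matrix, one row per sample, one column per coefficient.
#' @param y Response vector, `length(y) == nrow(Phi)`.
#' @param lower Per-coefficient lower bound: `0` for sign-constrained
#'   coefficients, `-Inf` for unconstrained ones.
#' @param labels Tibble with one row per column of `Phi`, carrying at least
#'   `column` (the column name), `role` (`"tf"`, `"mirna"`, `"ppi"`,
#'   `"translation"` or `"basal"`) and `regulator` (the regulator id, `NA`
#'   for structural terms).
#' @param prunable Logical vector: which columns backward elimination may
#'   remove.  Structural terms (basal level, translation rate) are not
#'   prunable.
#' @return An object of class `regression_problem`.
#' @export
regression_problem <- function(Phi, y, lower, labels, prunable) {
  Phi <- as.matrix(Phi)
  if (nrow(Phi) != length(y)) {
    stop_genpnp("`Phi` must have one row per response value.", "validation_error")
  }
  if (ncol(Phi) != length(lower) || ncol(Phi) != nrow(labels) ||
      ncol(Phi) != length(prunable)) {
    stop_genpnp(
      "`lower`, `labels` and `prunable` must describe every column of `Phi`.",
      "validation_error"
    )
  }
  colnames(Phi) <- labels$column
  structure(
    list(Phi = Phi, y = as.numeric(y), lower = as.numeric(lower),
         labels = labels, prunable = as.logical(prunable)),
    class = "regression_problem"
  )
}

#' @export
print.regression_problem <- function(x, ...) {
  cat(sprintf(
    "<regression_problem> %d samples x %d coefficients (%d sign-constrained, %d prunable)\n",
    nrow(x$Phi), ncol(x$Phi), sum(x$lower == 0), sum(x$prunable)
  ))
  invisible(x)
}

#' Sign-constrained least squares
#'
#' Minimises \eqn{\lVert y - \Phi\theta \rVert^2} subject to
#' \eqn{\theta_c \ge 0} for the constrained coefficients (those with lower
#' bound 0); the remaining coefficients are free.  This is the estimator used
#' for both network layers: miRNA repression abilities and basal levels are
#' constrained to be non-negative, transcription-factor and protein
#' interaction abilities are unconstrained.
#'
#' The free block is projected out with a (pivoted) QR decomposition and the
#' reduced problem is solved by Lawson-Hanson non-negative least squares
#' ([pracma::lsqnonneg()]); the free coefficients are then recovered by
#' ordinary least squares on the deflated response.  At the optimum the
#' Karush-Kuhn-Tucker conditions hold: the gradient vanishes along free and
#' interior coordinates and is non-negative along coordinates at their bound.
#'
#' @param problem A [regression_problem()].
#' @return A list with `theta` (named coefficient vector) and `sse` (residual
#'   sum of squares at the optimum).
#' @examples
#' p <- regression_problem(
#'   Phi = diag(2), y = c(1, -2), lower = c(-Inf, 0),
#'   labels = tibble::tibble(column = c("f", "c"), role = "tf", regulator = NA),
#'   prunable = c(TRUE, TRUE)
#' )
#' constrained_least_squares(p)
#' @export
constrained_least_squares <- function(problem) {
  Phi <- problem$Phi
  y <- problem$y
  if (!all(is.finite(Phi)) || !all(is.finite(y))) {
    stop_genpnp("Non-finite values in the regression problem.", "numeric_error")
  }
  if (ncol(Phi) == 0) {
    return(list(theta = setNames(numeric(0), character(0)), sse = sum(y^2)))
  }
  constrained <- problem$lower == 0
  theta <- numeric(ncol(Phi))

  if (!any(constrained)) {
    theta <- .ls_coef(Phi, y)
  } else if (all(constrained)) {
    theta <- pracma::lsqnonneg(Phi, y)$x
  } else {
    qf <- qr(Phi[, !constrained, drop = FALSE])
    rC <- qr.resid(qf, Phi[, constrained, drop = FALSE])
    ry <- qr.resid(qf, y)
    theta[constrained] <- pracma::lsqnonneg(rC, ry)$x
    theta[!constrained] <- .ls_coef(
      Phi[, !constrained, drop = FALSE],
      y - Phi[, constrained, drop = FALSE] %*% theta[constrained]
    )
  }
  # snap numerically-zero constrained coefficients onto the bound
  theta[constrained & abs(theta) < 1e-10] <- 0
  resid <- y - Phi %*% theta
  list(theta = setNames(as.numeric(theta), colnames(Phi)), sse = sum(resid^2))
}

# least-squares coefficients with rank-deficiency guard (aliased columns -> 0)
.ls_coef <- function(A, b) {
  fit <- qr(A)
  co <- qr.coef(fit, b)
  co[is.na(co)] <- 0
  as.numeric(co)
}
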