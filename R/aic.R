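#' Akaike information criterion for a least-squares fit
#'
#' Gaussian-likelihood AIC for a regression with `p` estimated coefficients
#' fitted to `L` samples:
#' \deqn{\mathrm{AIC} = L \ln(\mathrm{SSE}/L) + 2p.}
#' A floor of `1e-12` on the SSE keeps the score finite for interpolating
#' (noise-free) fits; all models whose residuals fall below the floor are
#' thereby compared on parameter count alone.
#'
#' @param sse Residual sum of squares (non-negative).
#' @param L Number of samples (positive).
#' @param p Number of estimated coefficients (non-negative).
#' @return The AIC score (smaller is better).
#' @export
aic_score <- function(sse, L, p) {
  if (L <= 0 || sse < 0 || p < 0) {
    stop_genpnp("`aic_score()` needs L > 0, sse >= 0 and p >= 0.", "domain_error")
  }
  L * log(max(sse, 1e-12) / L) + 2 * p
}

#' Prune a regression problem by backward elimination under AIC
#'
#' Detects the model order of a node (the number of genuinely active
#' regulators or interaction partners) by backward elimination.  The full
#' candidate model is fitted by [constrained_least_squares()]; the prunable
#' column whose coefficient has the smallest standardised magnitude
#' (\eqn{|\theta_c| \cdot \lVert \Phi_c \rVert}) is removed and the model
#' refitted, recording the AIC at each step down to the structural terms
#' only.  The model with minimal AIC along this path is returned, with ties
#' broken toward fewer parameters.  Structural columns (basal level,
#' translation rate) are never eliminated.
#'
#' If the candidate count makes the system under-determined (at least as
#' many columns as samples), candidates are pre-ranked by the absolute
#' correlation of their regressor column with the response and only the
#' strongest are entered, so that the stacked system stays over-determined.
#'
#' @param problem A [regression_problem()].
#' @return A list with `selected` (column names of the surviving model),
#'   `theta` (named coefficients), `sse`, `aic`, and `path`, a tibble
#'   recording `p`, `sse` and `aic` for every model visited.
#' @export
prune_by_aic <- function(problem) {
  L <- nrow(problem$Phi)
  keep <- rep(TRUE, ncol(problem$Phi))

  # over-determination guard: cap the number of entered candidates
  n_struct <- sum(!problem$prunable)
  max_cand <- max(L - 2 - n_struct, 0)
  if (sum(problem$prunable) > max_cand) {
    cand <- which(problem$prunable)
    score <- vapply(cand, function(j) {
      s <- suppressWarnings(abs(cor(problem$Phi[, j], problem$y)))
      if (is.na(s)) 0 else s
    }, numeric(1))
    drop <- cand[order(score, decreasing = TRUE)][-seq_len(max_cand)]
    if (max_cand == 0) drop <- cand
    keep[drop] <- FALSE
  }

  subproblem <- function(keep) {
    regression_problem(
      problem$Phi[, keep, drop = FALSE], problem$y, problem$lower[keep],
      problem$labels[keep, , drop = FALSE], problem$prunable[keep]
    )
  }

  path <- list()
  best <- NULL
  current <- keep
  repeat {
    fit <- constrained_least_squares(subproblem(current))
    aic <- aic_score(fit$sse, L, sum(current))
    path[[length(path) + 1]] <- tibble(p = sum(current), sse = fit$sse, aic = aic)
    # ties (to numerical tolerance) resolve toward the smaller model,
    # i.e. the later entry on the elimination path
    if (is.null(best) || aic <= best$aic - 1e-9 ||
        (abs(aic - best$aic) <= 1e-9 && sum(current) < sum(best$keep))) {
      best <- list(keep = current, theta = fit$theta, sse = fit$sse, aic = aic)
    }
    prunable_now <- which(current & problem$prunable)
    if (length(prunable_now) == 0) break
    std <- abs(fit$theta[match(prunable_now, which(current))]) *
      sqrt(colSums(problem$Phi[, prunable_now, drop = FALSE]^2))
    current[prunable_now[which.min(std)]] <- FALSE
  }

  list(
    selected = colnames(problem$Phi)[best$keep],
    theta = best$theta,
    sse = best$sse,
    aic = best$aic,
    path = dplyr::bind_rows(path)
  )
}
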