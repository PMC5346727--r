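# Independent oracles and small fixture builders used across the suite.

# Exhaustive active-set oracle for bound-constrained least squares:
# for every subset of the sign-constrained coefficients clamped to zero,
# solve the unconstrained problem on the remaining columns and keep the
# feasible solution with minimal SSE.  Exact for this convex problem.
cls_oracle <- function(Phi, y, lower) {
  p <- ncol(Phi)
  constrained <- which(lower == 0)
  best <- list(sse = Inf, theta = rep(0, p))
  subsets <- if (length(constrained) == 0) list(integer(0)) else {
    unlist(lapply(0:length(constrained), function(k)
      utils::combn(constrained, k, simplify = FALSE)), recursive = FALSE)
  }
  for (zero_set in subsets) {
    free <- setdiff(seq_len(p), zero_set)
    theta <- rep(0, p)
    if (length(free) > 0) {
      co <- qr.coef(qr(Phi[, free, drop = FALSE]), y)
      co[is.na(co)] <- 0
      theta[free] <- co
    }
    if (all(theta[constrained] >= -1e-9)) {
      sse <- sum((y - Phi %*% theta)^2)
      if (sse < best$sse - 1e-12) best <- list(sse = sse, theta = theta)
    }
  }
  best
}

# random small constrained-LS problem
random_problem <- function(seed) {
  withr::with_seed(seed, {
    L <- sample(3:8, 1)
    p <- sample(1:3, 1)
    Phi <- matrix(rnorm(L * p), L, p)
    y <- rnorm(L)
    lower <- ifelse(runif(p) < 0.5, 0, -Inf)
    labels <- tibble::tibble(column = paste0("c", seq_len(p)),
                             role = "tf", regulator = NA_character_)
    regression_problem(Phi, y, lower, labels, prunable = rep(TRUE, p))
  })
}

# smallest useful omics dataset: explicit matrices, one or two stages
tiny_dataset <- function(gene_expr, mirna_expr, methylation, stage) {
  omics_dataset(gene_expr, mirna_expr, methylation,
                tibble::tibble(sample = colnames(gene_expr), stage = stage))
}

# an identified network built directly from a ground truth (perfect recovery)
truth_as_identified <- function(truth, stage = "I") {
  edges <- truth_edges(truth, stage)
  nodes <- tibble::tibble(
    node = unique(c(edges$target, truth$roles$genes)),
    role = "gene", basal = 1, translation = NA_real_,
    sse = 0, aic = 0, order = 0L
  )
  identified_gen(edges, nodes, stage)
}

# reference generator fixture at the study conditions
fixture_truth <- function(seed, sigma_v = 0.1, sigma_w = 0.05) {
  generate_truth(generator_config(seed = seed, sigma_v = sigma_v,
                                  sigma_w = sigma_w))
}
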