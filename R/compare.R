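#' Differential promoter methylation between two stages
#'
#' Per gene, compares the methylation beta values of two stage groups with
#' a two-sample rank test and calls the gene differentially methylated when
#' the test is significant *and* the mean beta shift reaches `min_delta`
#' (both inclusive).  The direction is the sign of the mean difference
#' (stage B minus stage A): `hyper` means higher methylation in B.
#'
#' @param dataset An [omics_dataset()].
#' @param stage_a,stage_b Stage labels; each needs at least 3 samples.
#' @param genes Genes to test (default: all).  Genes absent from the
#'   methylation matrix are listed as untested.
#' @param alpha Significance level (default 0.05).
#' @param min_delta Minimal absolute mean beta difference (default 0.1).
#' @param test `"wilcoxon"` (default; no distributional assumption) or
#'   `"t"`.
#' @return A tibble `(gene, p, mean_a, mean_b, delta, called, direction,
#'   tested)`.
#' @export
differential_methylation <- function(dataset, stage_a, stage_b,
                                     genes = rownames(dataset$methylation),
                                     alpha = 0.05, min_delta = 0.1,
                                     test = c("wilcoxon", "t")) {
  test <- match.arg(test)
  sa <- stage_samples(dataset, stage_a)
  sb <- stage_samples(dataset, stage_b)
  check_group_sizes(sa, sb, stage_a, stage_b)
  rows <- purrr::map(genes, function(g) {
    if (!g %in% rownames(dataset$methylation)) {
      return(tibble(gene = g, p = NA_real_, mean_a = NA_real_,
                    mean_b = NA_real_, delta = NA_real_, called = FALSE,
                    direction = NA_character_, tested = FALSE))
    }
    a <- dataset$methylation[g, sa]; b <- dataset$methylation[g, sb]
    p <- two_group_p(a, b, test)
    delta <- mean(b) - mean(a)
    called <- !is.na(p) && p <= alpha && abs(delta) >= min_delta
    tibble(gene = g, p = p, mean_a = mean(a), mean_b = mean(b), delta = delta,
           called = called,
           direction = if (called) ifelse(delta > 0, "hyper", "hypo") else NA_character_,
           tested = TRUE)
  })
  dplyr::bind_rows(rows)
}

#' Differential miRNA expression between two stages
#'
#' Per miRNA, compares expression between the two stage groups; significant
#' miRNAs are labelled `up` or `down` in stage B relative to stage A.
#'
#' @inheritParams differential_methylation
#' @param mirnas miRNAs to test (default: all).
#' @return A tibble `(mirna, p, mean_a, mean_b, called, direction, tested)`.
#' @export
differential_mirna <- function(dataset, stage_a, stage_b,
                               mirnas = rownames(dataset$mirna_expr),
                               alpha = 0.05, test = c("wilcoxon", "t")) {
  test <- match.arg(test)
  sa <- stage_samples(dataset, stage_a)
  sb <- stage_samples(dataset, stage_b)
  check_group_sizes(sa, sb, stage_a, stage_b)
  rows <- purrr::map(mirnas, function(m) {
    if (!m %in% rownames(dataset$mirna_expr)) {
      return(tibble(mirna = m, p = NA_real_, mean_a = NA_real_,
                    mean_b = NA_real_, called = FALSE,
                    direction = NA_character_, tested = FALSE))
    }
    a <- dataset$mirna_expr[m, sa]; b <- dataset$mirna_expr[m, sb]
    p <- two_group_p(a, b, test)
    called <- !is.na(p) && p <= alpha
    tibble(mirna = m, p = p, mean_a = mean(a), mean_b = mean(b),
           called = called,
           direction = if (called) ifelse(mean(b) > mean(a), "up", "down")
                       else NA_character_,
           tested = TRUE)
  })
  dplyr::bind_rows(rows)
}

two_group_p <- function(a, b, test) {
  if (test == "t") stats::t.test(a, b)$p.value
  else suppressWarnings(stats::wilcox.test(a, b)$p.value)
}

check_group_sizes <- function(sa, sb, stage_a, stage_b) {
  if (length(sa) < 3 || length(sb) < 3) {
    stop_genpnp(sprintf("Stages '%s' and '%s' both need at least 3 samples.",
                        stage_a, stage_b), "validation_error")
  }
}

#' Edge-polarity consistency between two identified networks
#'
#' Over the edges surviving pruning in *both* networks, computes the
#' fraction whose coefficient signs agree (a surviving edge always has a
#' non-zero coefficient, so signs are well defined).  This is the statistic
#' used to validate networks identified from independent datasets against
#' each other.  The count of shared edges with changed sign is also
#' reported, so both readings of "consistency among unchanged-sign edges"
#' can be reconstructed.  With no shared edges the fraction is undefined
#' and reported as `NA` with `defined = FALSE`.
#'
#' @param gen_a,gen_b [identified_gen()] objects over overlapping node
#'   universes.
#' @return A one-row tibble `(consistency, n_shared, n_sign_agree,
#'   n_sign_changed, defined)`.
#' @export
polarity_consistency <- function(gen_a, gen_b) {
  key <- function(g) {
    e <- g$edges
    ppi <- e$edge_type == "ppi"
    tibble(
      source = ifelse(ppi, pmin(e$source, e$target), e$source),
      target = ifelse(ppi, pmax(e$source, e$target), e$target),
      edge_type = e$edge_type, coefficient = e$coefficient
    ) |>
      dplyr::group_by(.data$source, .data$target, .data$edge_type) |>
      dplyr::summarise(coefficient = .data$coefficient[1], .groups = "drop")
  }
  shared <- dplyr::inner_join(key(gen_a), key(gen_b),
                              by = c("source", "target", "edge_type"),
                              suffix = c("_a", "_b"))
  n <- nrow(shared)
  if (n == 0) {
    return(tibble(consistency = NA_real_, n_shared = 0L, n_sign_agree = 0L,
                  n_sign_changed = 0L, defined = FALSE))
  }
  agree <- sign(shared$coefficient_a) == sign(shared$coefficient_b)
  tibble(consistency = mean(agree), n_shared = n,
         n_sign_agree = sum(agree), n_sign_changed = sum(!agree),
         defined = TRUE)
}

#' Coefficient of determination between two sets of projection distances
#'
#' Regresses the projection distances of decomposition B on those of A over
#' the rows (node, role) common to both, by ordinary least squares, and
#' returns \eqn{R^2 = 1 - SS_{res}/SS_{tot}}.  Used to quantify how well
#' the principal structure found in one dataset reproduces in another.
#' Constant distances in A leave the regression undefined (`defined =
#' FALSE`).
#'
#' @param pnp_a,pnp_b [pnp_decompose()] results (or their `distances`
#'   tibbles).
#' @return A one-row tibble `(r2, n, defined)`.
#' @export
projection_distance_r2 <- function(pnp_a, pnp_b) {
  da <- if (inherits(pnp_a, "pnp_result")) pnp_a$distances else as_tibble(pnp_a)
  db <- if (inherits(pnp_b, "pnp_result")) pnp_b$distances else as_tibble(pnp_b)
  shared <- dplyr::inner_join(da[, c("node", "role", "distance")],
                              db[, c("node", "role", "distance")],
                              by = c("node", "role"), suffix = c("_a", "_b"))
  if (nrow(shared) < 3) {
    stop_genpnp("Need at least 3 common (node, role) rows.", "validation_error")
  }
  if (stats::sd(shared$distance_a) == 0) {
    return(tibble(r2 = NA_real_, n = nrow(shared), defined = FALSE))
  }
  fit <- stats::lm(distance_b ~ distance_a, data = shared)
  r2 <- 1 - sum(residuals(fit)^2) /
    sum((shared$distance_b - mean(shared$distance_b))^2)
  tibble(r2 = r2, n = nrow(shared), defined = TRUE)
}

#' Set differences between two core GENs
#'
#' Reports the shared, A-specific and B-specific core nodes (by role) and
#' induced edges (by edge type) of two extracted cores.
#'
#' @param core_a,core_b [extract_core()] results.
#' @return A list of two tibbles, `nodes` and `edges`, each with a
#'   `status` column (`shared`, `a_only`, `b_only`).
#' @export
compare_core_gens <- function(core_a, core_b) {
  na <- core_a$nodes[, c("node", "role")]
  nb <- core_b$nodes[, c("node", "role")]
  nodes <- dplyr::bind_rows(
    dplyr::mutate(dplyr::inner_join(na, nb, by = c("node", "role")), status = "shared"),
    dplyr::mutate(dplyr::anti_join(na, nb, by = c("node", "role")), status = "a_only"),
    dplyr::mutate(dplyr::anti_join(nb, na, by = c("node", "role")), status = "b_only")
  )
  ek <- function(core) dplyr::distinct(
    core$edges[, c("source", "target", "edge_type")])
  ea <- ek(core_a); eb <- ek(core_b)
  edges <- dplyr::bind_rows(
    dplyr::mutate(dplyr::inner_join(ea, eb, by = names(ea)), status = "shared"),
    dplyr::mutate(dplyr::anti_join(ea, eb, by = names(ea)), status = "a_only"),
    dplyr::mutate(dplyr::anti_join(eb, ea, by = names(ea)), status = "b_only")
  )
  list(nodes = nodes, edges = edges)
}

#' Filter a pathway-enrichment table
#'
#' Applies the reporting filter used for enriched-pathway tables: keep
#' terms with `p <= max_p` and at least `min_count` member proteins (both
#' inclusive).
#'
#' @param table Data frame with columns `term`, `count`, `p` (further
#'   columns are preserved).
#' @param max_p Maximal p-value (default 0.05, inclusive).
#' @param min_count Minimal member count (default 5, inclusive).
#' @return The filtered tibble, ordered by descending count then p.
#' @export
filter_enrichment_table <- function(table, max_p = 0.05, min_count = 5) {
  table <- as_tibble(table)
  if (!all(c("term", "count", "p") %in% names(table))) {
    stop_genpnp("Enrichment table needs columns term, count and p.",
                "format_error")
  }
  table |>
    dplyr::filter(.data$p <= max_p, .data$count >= min_count) |>
    dplyr::arrange(dplyr::desc(.data$count), .data$p)
}
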