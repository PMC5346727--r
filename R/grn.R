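#' Build the transcription-model regression for one gene
#'
#' Rearranges the methylation-attenuated transcription model of gene *i*
#' into linear-regression form.  For sample *n* the regression row is
#' \deqn{[\, y_{j,n} h(\beta_{i,n}) \;\cdots\; -s_{m,n} x_{i,n} \;\cdots\;
#'        h(\beta_{i,n}) \,]}
#' over the candidate TFs *j* and candidate miRNAs *m*, with response
#' \eqn{x_{i,n}}, so the parameter vector is \eqn{[a_{i1} \cdots b_{i1}
#' \cdots k_i]}.  The \eqn{-s x} regressor carries the repression sign, so
#' the non-negativity bound on \eqn{b_{im}} (and on the basal level
#' \eqn{k_i}) expresses that miRNA binding can only repress.  TF
#' coefficients are unbounded.  Candidate regulators equal to the gene
#' itself are excluded.
#'
#' @param gene Gene id (a row of the dataset's expression matrix).
#' @param dataset An [omics_dataset()].
#' @param candidates A [candidate_gen()].
#' @param samples Optional sample ids restricting the rows (default: all).
#' @return A [regression_problem()]; a gene without candidate regulators
#'   yields a problem holding only the basal column.
#' @export
build_grn_regression <- function(gene, dataset, candidates, samples = NULL) {
  if (!gene %in% rownames(dataset$gene_expr)) {
    stop_genpnp(sprintf("Gene '%s' is not in the dataset.", gene), "validation_error")
  }
  samples <- samples %||% colnames(dataset$gene_expr)
  x <- dataset$gene_expr[gene, samples]
  beta <- dataset$methylation[gene, samples]
  hb <- methylation_attenuation(beta)

  tfs <- candidates$tf_edges$source[candidates$tf_edges$target == gene]
  tfs <- sort(intersect(setdiff(tfs, gene), rownames(dataset$gene_expr)))
  mirnas <- candidates$mirna_edges$source[candidates$mirna_edges$target == gene]
  mirnas <- sort(intersect(mirnas, rownames(dataset$mirna_expr)))

  tf_block <- if (length(tfs)) {
    t(dataset$gene_expr[tfs, samples, drop = FALSE]) * hb
  } else matrix(0, length(samples), 0)
  mi_block <- if (length(mirnas)) {
    -t(dataset$mirna_expr[mirnas, samples, drop = FALSE]) * x
  } else matrix(0, length(samples), 0)

  Phi <- cbind(tf_block, mi_block, basal = hb)
  labels <- tibble(
    column = c(if (length(tfs)) paste0("tf:", tfs),
               if (length(mirnas)) paste0("mirna:", mirnas), "basal"),
    role = c(rep("tf", length(tfs)), rep("mirna", length(mirnas)), "basal"),
    regulator = c(tfs, mirnas, NA_character_)
  )
  regression_problem(
    Phi, x,
    lower = c(rep(-Inf, length(tfs)), rep(0, length(mirnas)), 0),
    labels = labels,
    prunable = c(rep(TRUE, length(tfs) + length(mirnas)), FALSE)
  )
}

#' Identify the stage-specific gene regulatory network
#'
#' Fits the methylation-attenuated transcription model for every gene of
#' the dataset over the samples of one stage, pruning false-positive
#' candidate regulators by [prune_by_aic()].  Genes absent from the
#' candidate network receive a basal-only fit.  The result depends only on
#' the (feature, sample) values, not on sample order.
#'
#' @param dataset An [omics_dataset()].
#' @param candidates A [candidate_gen()].
#' @param stage Canonical stage label; the stage must contribute at least
#'   3 samples.
#' @param include_normals Pool the normal samples with the stage's tumour
#'   samples (default: tumour-only, each stage's network fitted from its
#'   own samples).
#' @param genes Genes to fit (default: all rows of the expression matrix).
#' @return An [identified_gen()] holding the gene-side network.
#' @export
identify_grn <- function(dataset, candidates, stage, include_normals = FALSE,
                         genes = rownames(dataset$gene_expr)) {
  samples <- stage_samples(dataset, stage, include_normals)
  if (length(samples) < 3) {
    stop_genpnp(sprintf("Stage '%s' has fewer than 3 samples.", stage),
                "validation_error")
  }
  fits <- purrr::map(genes, function(g) {
    fit <- prune_by_aic(build_grn_regression(g, dataset, candidates, samples))
    lab <- tibble(column = fit$selected, coefficient = unname(fit$theta))
    kept <- lab[lab$column != "basal", ]
    edges <- if (nrow(kept)) {
      tibble(
        source = sub("^(tf|mirna):", "", kept$column),
        target = g,
        edge_type = sub(":.*$", "", kept$column),
        coefficient = ifelse(grepl("^mirna:", kept$column),
                             -kept$coefficient, kept$coefficient),
        stage = stage
      )
    } else NULL
    node <- tibble(
      node = g, role = "gene",
      basal = unname(fit$theta[fit$selected == "basal"]),
      translation = NA_real_,
      sse = fit$sse, aic = fit$aic, order = nrow(kept)
    )
    list(edges = edges, node = node)
  })
  identified_gen(
    edges = bind_edges(fits),
    nodes = dplyr::bind_rows(lapply(fits, `[[`, "node")),
    stage = stage
  )
}

bind_edges <- function(fits) {
  e <- dplyr::bind_rows(lapply(fits, `[[`, "edges"))
  if (nrow(e) == 0) {
    e <- tibble(source = character(0), target = character(0),
                edge_type = character(0), coefficient = numeric(0),
                stage = character(0))
  }
  # drop coefficients pruned to exactly zero by the bound: a zero ability
  # is no edge
  e[e$coefficient != 0, ]
}
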