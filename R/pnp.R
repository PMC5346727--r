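#' Assemble the combined network matrix of a GEN
#'
#' Stacks the identified coefficients into the combined network matrix
#' \eqn{H} with \eqn{2N + M} rows and \eqn{N} columns, where \eqn{N} is the
#' number of genes/proteins (one shared id space) and \eqn{M} the number of
#' miRNAs.  Column *i* is target gene *i*; rows are grouped by regulator
#' role in fixed block order:
#' rows \eqn{1..N} hold protein interactions \eqn{c_{i,k}},
#' rows \eqn{N+1..2N} hold TF regulations \eqn{a_{i,k-N}},
#' rows \eqn{2N+1..2N+M} hold miRNA repressions \eqn{-b_{i,k-2N}}.
#' Entries without a surviving edge are 0; the miRNA block is therefore
#' non-positive.
#'
#' @param gen An [identified_gen()].
#' @param genes Character vector fixing the gene/protein id space and its
#'   order (length \eqn{N}).
#' @param mirnas Character vector fixing the miRNA ids (length \eqn{M}).
#' @return An object of class `network_matrix`: list with the matrix `H`,
#'   `row_info` (tibble `k`, `node`, `role`) and `col_nodes`.
#' @export
assemble_network_matrix <- function(gen, genes, mirnas) {
  N <- length(genes); M <- length(mirnas)
  H <- matrix(0, 2 * N + M, N)
  gidx <- setNames(seq_len(N), genes)
  midx <- setNames(seq_len(M), mirnas)

  place <- function(edges, row_of, offset) {
    if (nrow(edges) == 0) return()
    bad <- !(edges$source %in% names(row_of)) | !(edges$target %in% names(gidx))
    if (any(bad)) {
      stop_genpnp(
        sprintf("Edge %s -> %s lies outside the node universe.",
                edges$source[bad][1], edges$target[bad][1]),
        "assembly_error"
      )
    }
    H[cbind(offset + row_of[edges$source], gidx[edges$target])] <<- edges$coefficient
  }
  place(gen$edges[gen$edges$edge_type == "ppi", ], gidx, 0)
  place(gen$edges[gen$edges$edge_type == "tf", ], gidx, N)
  place(gen$edges[gen$edges$edge_type == "mirna", ], midx, 2 * N)

  row_info <- tibble(
    k = seq_len(2 * N + M),
    node = c(genes, genes, mirnas),
    role = c(rep("protein", N), rep("gene", N), rep("mirna", M))
  )
  structure(list(H = H, row_info = row_info, col_nodes = genes, N = N, M = M),
            class = "network_matrix")
}

#' @export
print.network_matrix <- function(x, ...) {
  cat(sprintf("<network_matrix> (2N+M) x N = %d x %d, %d non-zero entries\n",
              nrow(x$H), ncol(x$H), sum(x$H != 0)))
  invisible(x)
}

#' Principal network projection of a combined network matrix
#'
#' Decomposes \eqn{H = U D V^T} by singular value decomposition and
#' measures each network node's participation in the principal network
#' structure.  The eigenexpression fraction of component *m* is
#' \eqn{E_m = d_m^2 / \sum_n d_n^2}; the smallest number `M_sel` of leading
#' components whose cumulative eigenexpression reaches the `energy`
#' threshold is retained (the threshold is on normalized energy, so 0.85
#' keeps the components jointly carrying 85% of the matrix energy).  Each
#' row \eqn{h_{k,:}} of `H` is projected onto the retained right singular
#' vectors, \eqn{P(k,m) = h_{k,:} v_{:,m}}, and summarized by the 2-norm
#' projection distance
#' \deqn{D(k) = \Big(\sum_{m \le M_{sel}} P(k,m)^2\Big)^{1/2}.}
#' Nodes with \eqn{D(k)} near zero are essentially orthogonal to the
#' principal structure; nodes with large \eqn{D(k)} carry it.
#'
#' @param nm A [assemble_network_matrix()] result (or a bare matrix, in
#'   which case rows are labelled positionally).
#' @param energy Cumulative eigenexpression threshold in `(0, 1]`
#'   (default 0.85); `energy = 1` retains every non-degenerate component,
#'   making \eqn{D(k)} the Euclidean row norm.
#' @return An object of class `pnp_result`: singular values `d`,
#'   eigenexpression fractions `energy_fraction`, selected component count
#'   `m_selected`, the projection matrix `projections`, and `distances`, a
#'   tibble `(k, node, role, distance)`.
#' @export
pnp_decompose <- function(nm, energy = 0.85) {
  if (is.matrix(nm)) {
    nm <- list(
      H = nm,
      row_info = tibble(k = seq_len(nrow(nm)),
                        node = as.character(seq_len(nrow(nm))),
                        role = "row"),
      col_nodes = as.character(seq_len(ncol(nm)))
    )
  }
  H <- nm$H
  if (all(H == 0)) {
    stop_genpnp("The combined network matrix is all zero; nothing to decompose.",
                "decomposition_error")
  }
  if (energy <= 0 || energy > 1) {
    stop_genpnp("`energy` must lie in (0, 1].", "parameter_error")
  }
  sv <- svd(H, nu = 0)
  d <- sv$d
  E <- d^2 / sum(d^2)
  m_sel <- which(cumsum(E) >= energy - 1e-12)[1]
  P <- H %*% sv$v
  D <- sqrt(rowSums(P[, seq_len(m_sel), drop = FALSE]^2))
  structure(
    list(
      d = d, energy_fraction = E, m_selected = m_sel, energy = energy,
      projections = P, v = sv$v,
      distances = dplyr::mutate(nm$row_info, distance = D)
    ),
    class = "pnp_result"
  )
}

#' @export
print.pnp_result <- function(x, ...) {
  cat(sprintf(
    "<pnp_result> %d components selected of %d (cumulative energy %.3f >= %.2f)\n",
    x$m_selected, length(x$d), sum(x$energy_fraction[seq_len(x$m_selected)]),
    x$energy
  ))
  invisible(x)
}

#' @export
tidy.pnp_result <- function(x, ...) x$distances

#' @export
glance.pnp_result <- function(x, ...) {
  tibble(
    n_components = length(x$d),
    m_selected = x$m_selected,
    energy = x$energy,
    energy_captured = sum(x$energy_fraction[seq_len(x$m_selected)]),
    top_singular_value = x$d[1]
  )
}

#' Extract the core GEN from projection distances
#'
#' Selects the core proteins, core genes and core miRNAs of a decomposed
#' network, either by role-specific absolute thresholds on the projection
#' distance (`D(k) >= th`, inclusive) or -- the default, since absolute
#' thresholds depend on the coefficient scale of the study -- by keeping a
#' fixed number of top-ranked nodes per role.  Ties in distance are broken
#' by lexicographic node id.  If the identified network is supplied, the
#' subnetwork induced by the core nodes (edges whose endpoints are both
#' core, miRNA sources checked against the core miRNAs and gene/protein
#' endpoints against the union of core proteins and core genes) is
#' attached.
#'
#' @param pnp A [pnp_decompose()] result.
#' @param mode `"top"` (counts per role) or `"threshold"` (absolute
#'   distances `th1` for proteins, `th2` for genes, `th3` for miRNAs).
#' @param top_counts Named integer vector with entries `protein`, `gene`,
#'   `mirna` (defaults 30, 30, 15).
#' @param thresholds Named numeric vector with entries `protein`, `gene`,
#'   `mirna`; all must be non-negative.
#' @param gen Optional [identified_gen()] for the induced subnetwork.
#' @return An object of class `core_gen`: `nodes` tibble
#'   `(node, role, distance, rank)` and `edges` tibble.
#' @export
extract_core <- function(pnp, mode = c("top", "threshold"),
                         top_counts = c(protein = 30, gene = 30, mirna = 15),
                         thresholds = NULL, gen = NULL) {
  mode <- match.arg(mode)
  dist <- pnp$distances
  if (mode == "threshold") {
    if (is.null(thresholds) || !all(c("protein", "gene", "mirna") %in% names(thresholds))) {
      stop_genpnp("`thresholds` must name protein, gene and mirna values.",
                  "parameter_error")
    }
    if (any(thresholds < 0)) {
      stop_genpnp("Thresholds must be non-negative.", "parameter_error")
    }
  }
  pick <- function(role) {
    rows <- dist[dist$role == role, ]
    rows <- rows[order(-rows$distance, rows$node), ]
    rows$rank <- seq_len(nrow(rows))
    if (mode == "threshold") {
      rows[rows$distance >= thresholds[[role]], ]
    } else {
      head(rows, top_counts[[role]])
    }
  }
  nodes <- dplyr::bind_rows(pick("protein"), pick("gene"), pick("mirna"))

  edges <- NULL
  if (!is.null(gen) && nrow(nodes) > 0) {
    core_genes <- nodes$node[nodes$role %in% c("protein", "gene")]
    core_mirnas <- nodes$node[nodes$role == "mirna"]
    e <- gen$edges
    keep <- ifelse(
      e$edge_type == "mirna",
      e$source %in% core_mirnas & e$target %in% core_genes,
      e$source %in% core_genes & e$target %in% core_genes
    )
    edges <- e[keep, ]
  }
  if (is.null(edges)) {
    edges <- tibble(source = character(0), target = character(0),
                    edge_type = character(0), coefficient = numeric(0),
                    stage = character(0))
  }
  structure(
    list(nodes = nodes, edges = edges, mode = mode,
         params = if (mode == "top") top_counts else thresholds),
    class = "core_gen"
  )
}

#' @export
print.core_gen <- function(x, ...) {
  tab <- table(factor(x$nodes$role, levels = c("protein", "gene", "mirna")))
  cat(sprintf(
    "<core_gen> %d core proteins, %d core genes, %d core miRNAs; %d induced edges\n",
    tab[["protein"]], tab[["gene"]], tab[["mirna"]], nrow(x$edges)
  ))
  invisible(x)
}

#' @export
tidy.core_gen <- function(x, ...) x$nodes

#' Differential-expression significance of core components
#'
#' For every core component, tests whether its expression differs between
#' the tumour stage and the normal samples with a two-sample Wilcoxon
#' rank-sum test (genes and proteins on the gene-expression matrix, miRNAs
#' on the miRNA matrix).  The fraction of components with `p <= alpha` is
#' attached as the `"significant_fraction"` attribute; a core extracted
#' from informative projection distances is expected to consist almost
#' entirely of differentially expressed components.
#'
#' @param core A [extract_core()] result.
#' @param dataset An [omics_dataset()] containing normal samples.
#' @param stage Tumour stage to compare against normal.
#' @param alpha Significance level (default 0.05).
#' @return A tibble `(node, role, p, significant)` with attribute
#'   `significant_fraction`.
#' @export
component_significance <- function(core, dataset, stage, alpha = 0.05) {
  normals <- dataset$stages$sample[dataset$stages$stage == "normal"]
  if (length(normals) == 0) {
    stop_genpnp("No normal samples in the dataset.", "validation_error")
  }
  tumour <- stage_samples(dataset, stage)
  nodes <- core$nodes
  if (nrow(nodes) == 0) {
    out <- tibble(node = character(0), role = character(0),
                  p = numeric(0), significant = logical(0))
    attr(out, "significant_fraction") <- NA_real_
    return(out)
  }
  p <- purrr::map_dbl(seq_len(nrow(nodes)), function(i) {
    m <- if (nodes$role[i] == "mirna") dataset$mirna_expr else dataset$gene_expr
    if (!nodes$node[i] %in% rownames(m)) return(NA_real_)
    stats::wilcox.test(m[nodes$node[i], tumour], m[nodes$node[i], normals])$p.value
  })
  out <- tibble(node = nodes$node, role = nodes$role, p = p,
                significant = !is.na(p) & p <= alpha)
  attr(out, "significant_fraction") <- mean(out$significant[!is.na(out$p)])
  out
}
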