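#' Construct an identified GEN
#'
#' The identified (pruned) genetic and epigenetic network for one stage: the
#' edges surviving AIC order detection, with their fitted coefficients, and
#' a per-node table of structural terms and fit statistics.
#'
#' Edge coefficients follow the sign convention of the combined network
#' matrix: TF edges carry the signed binding ability \eqn{a_{ij}}, miRNA
#' edges carry the (non-positive) repression \eqn{-b_{im}}, and
#' protein-protein edges carry the signed interaction ability \eqn{c_{pq}}
#' estimated with `target` as the modelled protein and `source` as its
#' partner.
#'
#' @param edges Tibble with columns `source`, `target`,
#'   `edge_type` (`"tf"`, `"mirna"` or `"ppi"`), `coefficient`, `stage`.
#' @param nodes Tibble with columns `node`, `role` (`"gene"` or
#'   `"protein"`), `basal`, `translation` (`NA` unless fitted in
#'   full-protein mode), `sse`, `aic`, `order`.
#' @param stage Canonical stage label the network was fitted on.
#' @return An object of class `identified_gen`.
#' @export
identified_gen <- function(edges, nodes, stage) {
  edges <- as_tibble(edges)
  nodes <- as_tibble(nodes)
  need_e <- c("source", "target", "edge_type", "coefficient", "stage")
  if (!all(need_e %in% names(edges))) {
    stop_genpnp("`edges` must have columns source, target, edge_type, coefficient, stage.",
                "format_error")
  }
  if (!"translation" %in% names(nodes)) nodes$translation <- NA_real_
  need_n <- c("node", "role", "basal", "translation", "sse", "aic", "order")
  if (!all(need_n %in% names(nodes))) {
    stop_genpnp("`nodes` must have columns node, role, basal, sse, aic, order.",
                "format_error")
  }
  bad <- !edges$edge_type %in% c("tf", "mirna", "ppi")
  if (any(bad)) {
    stop_genpnp(sprintf("Unknown edge_type: %s",
                        paste(unique(edges$edge_type[bad]), collapse = ", ")),
                "format_error")
  }
  if (any(edges$edge_type == "mirna" & edges$coefficient > 0)) {
    stop_genpnp("miRNA edge coefficients are stored as repressions and must be <= 0.",
                "validation_error")
  }
  structure(
    list(edges = edges[, need_e], nodes = nodes[, need_n], stage = stage),
    class = "identified_gen"
  )
}

#' @export
print.identified_gen <- function(x, ...) {
  tab <- table(factor(x$edges$edge_type, levels = c("tf", "mirna", "ppi")))
  cat(sprintf(
    "<identified_gen> stage %s: %d nodes, %d edges (tf %d, mirna %d, ppi %d)\n",
    x$stage, nrow(x$nodes), nrow(x$edges), tab[["tf"]], tab[["mirna"]], tab[["ppi"]]
  ))
  invisible(x)
}

#' Merge gene-side and protein-side fits into one network
#'
#' @param ... `identified_gen` objects fitted on the same stage (typically
#'   the transcriptional fit from [identify_grn()] and the protein fit from
#'   [identify_ppin()]).
#' @return A single [identified_gen()].
#' @export
merge_identified_gen <- function(...) {
  parts <- list(...)
  stages <- unique(vapply(parts, function(p) p$stage, character(1)))
  if (length(stages) != 1) {
    stop_genpnp("Cannot merge networks fitted on different stages.", "validation_error")
  }
  identified_gen(
    edges = dplyr::bind_rows(lapply(parts, `[[`, "edges")),
    nodes = dplyr::bind_rows(lapply(parts, `[[`, "nodes")),
    stage = stages
  )
}

#' Write / read an identified GEN
#'
#' The network is serialized as two tab-separated files: the edge table at
#' `path` with columns `(source, target, edge_type, coefficient, stage)` and
#' the node table with columns
#' `(node, role, basal, translation, sse, aic, order)` at `nodes_path`
#' (default: `path` with a `_nodes.tsv` suffix).  Coefficients are written
#' at full precision so that `read_identified_gen(write_identified_gen(g))`
#' reproduces `g` exactly.
#'
#' @param gen An [identified_gen()].
#' @param path Path of the edge-table TSV.
#' @param nodes_path Path of the node-table TSV.
#' @return `write_identified_gen()` returns the two paths invisibly;
#'   `read_identified_gen()` returns an [identified_gen()].
#' @export
write_identified_gen <- function(gen, path,
                                 nodes_path = default_nodes_path(path)) {
  readr::write_tsv(gen$edges, path, progress = FALSE)
  readr::write_tsv(gen$nodes, nodes_path, progress = FALSE)
  invisible(c(path, nodes_path))
}

default_nodes_path <- function(path) {
  sub("(\\.tsv)?$", "_nodes.tsv", path)
}

#' @rdname write_identified_gen
#' @param stage Stage label; by default recovered from the edge table, or
#'   required when the network has no edges.
#' @export
read_identified_gen <- function(path, nodes_path = default_nodes_path(path),
                                stage = NULL) {
  edges <- readr::read_tsv(
    path,
    col_types = readr::cols(
      source = readr::col_character(), target = readr::col_character(),
      edge_type = readr::col_character(), coefficient = readr::col_double(),
      stage = readr::col_character()
    ),
    progress = FALSE
  )
  nodes <- readr::read_tsv(
    nodes_path,
    col_types = readr::cols(
      node = readr::col_character(), role = readr::col_character(),
      basal = readr::col_double(), translation = readr::col_double(),
      sse = readr::col_double(), aic = readr::col_double(),
      order = readr::col_integer()
    ),
    progress = FALSE
  )
  if (is.null(stage)) {
    stage <- unique(edges$stage)
    if (length(stage) == 0) stage <- NA_character_
  }
  identified_gen(edges, nodes, stage)
}

#' @export
tidy.identified_gen <- function(x, ...) x$edges

#' @export
glance.identified_gen <- function(x, ...) {
  tibble(
    stage = x$stage,
    n_nodes = nrow(x$nodes),
    n_edges = nrow(x$edges),
    n_tf = sum(x$edges$edge_type == "tf"),
    n_mirna = sum(x$edges$edge_type == "mirna"),
    n_ppi = sum(x$edges$edge_type == "ppi"),
    total_sse = sum(x$nodes$sse),
    mean_order = mean(x$nodes$order)
  )
}
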