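#' Assemble a candidate GEN
#'
#' The candidate genetic and epigenetic network holds the regulatory
#' associations mined from interaction databases *before* data-driven
#' pruning: TF-to-gene and miRNA-to-gene directed edges and unordered
#' protein-protein pairs.  Edges are deduplicated, protein pairs are
#' canonicalized (lexicographically smaller id first) and self-edges are
#' dropped with a warning, since the structural models exclude
#' self-regulation and self-interaction.
#'
#' @param tf_edges Tibble/data frame with columns `source` (TF gene id) and
#'   `target` (target gene id); extra columns are ignored.
#' @param mirna_edges Tibble with columns `source` (miRNA id), `target`
#'   (gene id).
#' @param ppi_edges Tibble with columns `source`, `target` (protein ids,
#'   unordered).
#' @return An object of class `candidate_gen` with tibbles `tf_edges`,
#'   `mirna_edges` and `ppi_edges` (the latter canonical with
#'   `source <= target`).
#' @export
candidate_gen <- function(tf_edges = NULL, mirna_edges = NULL, ppi_edges = NULL) {
  norm_directed <- function(e, what) {
    e <- normalize_edges(e, what)
    self <- e$source == e$target
    if (any(self)) {
      warn_genpnp(sprintf("%d self-edge(s) dropped from %s.", sum(self), what),
                  "self_edge_warning")
      e <- e[!self, ]
    }
    dplyr::distinct(e)
  }
  tf <- norm_directed(tf_edges, "tf_edges")
  mi <- normalize_edges(mirna_edges, "mirna_edges")
  mi <- dplyr::distinct(mi)
  pp <- norm_directed(ppi_edges, "ppi_edges")
  pp <- dplyr::distinct(canonical_pairs(pp))

  structure(list(tf_edges = tf, mirna_edges = mi, ppi_edges = pp),
            class = "candidate_gen")
}

normalize_edges <- function(e, what) {
  if (is.null(e)) return(tibble(source = character(0), target = character(0)))
  e <- as_tibble(e)
  if (ncol(e) < 2) {
    stop_genpnp(sprintf("%s needs two id columns.", what), "format_error")
  }
  if (!all(c("source", "target") %in% names(e))) names(e)[1:2] <- c("source", "target")
  tibble(source = as.character(e$source), target = as.character(e$target))
}

canonical_pairs <- function(e) {
  tibble(
    source = pmin(e$source, e$target),
    target = pmax(e$source, e$target)
  )
}

#' @export
print.candidate_gen <- function(x, ...) {
  cat(sprintf(
    "<candidate_gen> %d TF-gene, %d miRNA-gene, %d protein-protein candidate edges\n",
    nrow(x$tf_edges), nrow(x$mirna_edges), nrow(x$ppi_edges)
  ))
  invisible(x)
}

read_edge_tsv <- function(path, what) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  probs <- readr::problems(df)
  if (nrow(probs) > 0) {
    stop_genpnp(
      sprintf("Malformed row in %s ('%s'), line %d: %s",
              what, path, probs$row[1] + 1L, probs$expected[1]),
      "format_error"
    )
  }
  if (ncol(df) < 2 || any(is.na(df[[1]])) || any(is.na(df[[2]]))) {
    stop_genpnp(sprintf("Edge list '%s' needs two complete id columns.", path),
                "format_error")
  }
  df
}

#' Read a candidate GEN from TSV edge lists
#'
#' Each file is tab-separated with two id columns (`source`, `target`; any
#' further annotation columns are ignored).
#'
#' @param tf_path,mirna_path,ppi_path Paths to the TF-gene, miRNA-gene and
#'   protein-protein edge lists.
#' @return A [candidate_gen()].
#' @export
read_candidate_gen <- function(tf_path, mirna_path, ppi_path) {
  candidate_gen(
    tf_edges = read_edge_tsv(tf_path, "tf_edges"),
    mirna_edges = read_edge_tsv(mirna_path, "mirna_edges"),
    ppi_edges = read_edge_tsv(ppi_path, "ppi_edges")
  )
}

#' Write a candidate GEN as TSV edge lists
#'
#' @param candidates A [candidate_gen()].
#' @param dir Output directory (created if missing).
#' @return Paths of `tf_edges.tsv`, `mirna_edges.tsv`, `ppi_edges.tsv`,
#'   invisibly.
#' @export
write_candidate_gen <- function(candidates, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, c("tf_edges.tsv", "mirna_edges.tsv", "ppi_edges.tsv"))
  readr::write_tsv(candidates$tf_edges, paths[1], progress = FALSE)
  readr::write_tsv(candidates$mirna_edges, paths[2], progress = FALSE)
  readr::write_tsv(candidates$ppi_edges, paths[3], progress = FALSE)
  invisible(paths)
}
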