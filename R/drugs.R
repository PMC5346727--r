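#' Read a drug-gene interaction table
#'
#' Reads a local drug-gene interaction export (one row per interaction)
#' with columns `drug`, `gene` and optionally `interaction_type`; fully
#' duplicated rows are dropped.
#'
#' @param path TSV path.
#' @return A tibble `(drug, gene, interaction_type)`.
#' @export
read_drug_gene_table <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("drug", "gene") %in% names(df))) names(df)[1:2] <- c("drug", "gene")
  if (!"interaction_type" %in% names(df)) df$interaction_type <- NA_character_
  dplyr::distinct(as_tibble(df)[, c("drug", "gene", "interaction_type")])
}

#' Select drugs specific to network target genes
#'
#' For each designated target gene, ranks the drugs that interact with it
#' by how few *other* genes of the supplied network gene set they also
#' interact with (their off-target count).  A drug touching no other
#' network gene is flagged `specific` -- the operational reading of
#' selecting compounds that hit one marker gene with minimal side effects
#' on the rest of the network.  Ordering is deterministic: off-target
#' count ascending, then drug name.
#'
#' @param drug_table Tibble `(drug, gene, interaction_type)`, e.g. from
#'   [read_drug_gene_table()].
#' @param targets Character vector of target gene ids (must be a subset of
#'   `network_genes`).
#' @param network_genes Character vector: the network gene set against
#'   which side effects are counted.
#' @param interaction_types Optional filter on `interaction_type`
#'   (default: all rows count).
#' @return A tibble `(target, drug, off_target_count, specific)`; targets
#'   without any interacting drug yield no rows and a warning.
#' @export
select_specific_drugs <- function(drug_table, targets, network_genes,
                                  interaction_types = NULL) {
  drug_table <- dplyr::distinct(as_tibble(drug_table))
  if (!all(targets %in% network_genes)) {
    stop_genpnp("Every target must be part of `network_genes`.", "validation_error")
  }
  if (!is.null(interaction_types)) {
    drug_table <- drug_table[drug_table$interaction_type %in% interaction_types, ]
  }
  tab <- dplyr::distinct(drug_table[, c("drug", "gene")])
  rows <- purrr::map(targets, function(tg) {
    hits <- unique(tab$drug[tab$gene == tg])
    if (length(hits) == 0) {
      warn_genpnp(sprintf("No drug interacts with target '%s'.", tg),
                  "empty_target_warning")
      return(NULL)
    }
    off <- vapply(hits, function(d) {
      length(intersect(tab$gene[tab$drug == d], setdiff(network_genes, tg)))
    }, integer(1), USE.NAMES = FALSE)
    tibble(target = tg, drug = hits, off_target_count = off,
           specific = off == 0L) |>
      dplyr::arrange(.data$off_target_count, .data$drug)
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    out <- tibble(target = character(0), drug = character(0),
                  off_target_count = integer(0), specific = logical(0))
  }
  out
}

#' Combine the top drug per target into a multi-drug report
#'
#' Picks each target's top-ranked drug (fewest off-target interactions,
#' ties resolved lexicographically) and emits one `(drug, target)` row per
#' target -- the layout of a multi-drug design table.  Targets without
#' candidates are omitted with a warning, yielding a partial report.
#'
#' @param selection Output of [select_specific_drugs()].
#' @param targets Targets the report should cover (default: those present
#'   in `selection`).
#' @return A tibble `(drug, target, off_target_count, specific)`.
#' @export
multi_drug_report <- function(selection, targets = unique(selection$target)) {
  missing <- setdiff(targets, selection$target)
  if (length(missing) > 0) {
    warn_genpnp(sprintf("No candidate drug for target(s): %s; report is partial.",
                        paste(missing, collapse = ", ")),
                "partial_report_warning")
  }
  selection |>
    dplyr::filter(.data$target %in% targets) |>
    dplyr::group_by(.data$target) |>
    dplyr::arrange(.data$off_target_count, .data$drug, .by_group = TRUE) |>
    dplyr::slice(1) |>
    dplyr::ungroup() |>
    dplyr::select("drug", "target", "off_target_count", "specific")
}
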