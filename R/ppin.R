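#' Build the protein-interaction regression for one protein
#'
#' Rearranges the bilinear protein-interaction model of protein *p* into
#' regression form.  The interaction of proteins *p* and *q* is
#' proportional to the product of their abundances, so each candidate
#' partner contributes a regressor \eqn{y_{q,n} y_{p,n}}.
#'
#' In `"full"` mode (simultaneous protein and mRNA measurements) the row is
#' \eqn{[\, y_{q,n} y_{p,n} \cdots\; x_{p,n} \;\; 1 \,]} with parameters
#' \eqn{[c_{pq} \cdots e_p \; h_p]}: interaction abilities (signed), the
#' translation rate \eqn{e_p} and the basal level \eqn{h_p \ge 0}.  In
#' `"mrna_proxy"` mode (the default, matching the common situation where
#' only mRNA is measured genome-wide) protein abundance is replaced by the
#' corresponding mRNA expression; the translation rate then multiplies the
#' response itself and cannot be identified, so the translation column is
#' omitted and the parameters reduce to \eqn{[c_{pq} \cdots h_p]}.
#'
#' @param protein Protein id.
#' @param dataset An [omics_dataset()]; in proxy mode its `gene_expr` rows
#'   stand in for protein abundance.
#' @param candidates A [candidate_gen()]; partners are the protein's
#'   neighbours in the unordered candidate PPI edge set (the protein itself
#'   excluded).
#' @param mode `"mrna_proxy"` or `"full"`.
#' @param protein_expr Protein-abundance matrix (proteins x samples),
#'   required in full mode.
#' @param samples Optional sample ids restricting the rows.
#' @return A [regression_problem()].
#' @export
build_ppin_regression <- function(protein, dataset, candidates,
                                  mode = c("mrna_proxy", "full"),
                                  protein_expr = NULL, samples = NULL) {
  mode <- match.arg(mode)
  if (mode == "full" && is.null(protein_expr)) {
    stop_genpnp("Full-protein mode needs a `protein_expr` matrix.", "mode_error")
  }
  samples <- samples %||% colnames(dataset$gene_expr)
  abundance <- if (mode == "full") protein_expr else dataset$gene_expr
  if (!protein %in% rownames(abundance)) {
    stop_genpnp(sprintf("Protein '%s' is not in the abundance matrix.", protein),
                "validation_error")
  }
  yp <- abundance[protein, samples]

  pp <- candidates$ppi_edges
  partners <- c(pp$target[pp$source == protein], pp$source[pp$target == protein])
  partners <- sort(intersect(setdiff(unique(partners), protein), rownames(abundance)))

  partner_block <- if (length(partners)) {
    t(abundance[partners, samples, drop = FALSE]) * yp
  } else matrix(0, length(samples), 0)

  if (mode == "full") {
    xp <- dataset$gene_expr[protein, samples]
    Phi <- cbind(partner_block, translation = xp, basal = 1)
    labels <- tibble(
      column = c(if (length(partners)) paste0("ppi:", partners),
                 "translation", "basal"),
      role = c(rep("ppi", length(partners)), "translation", "basal"),
      regulator = c(partners, NA, NA)
    )
    lower <- c(rep(-Inf, length(partners)), -Inf, 0)
    prunable <- c(rep(TRUE, length(partners)), FALSE, FALSE)
  } else {
    Phi <- cbind(partner_block, basal = 1)
    labels <- tibble(
      column = c(if (length(partners)) paste0("ppi:", partners), "basal"),
      role = c(rep("ppi", length(partners)), "basal"),
      regulator = c(partners, NA)
    )
    lower <- c(rep(-Inf, length(partners)), 0)
    prunable <- c(rep(TRUE, length(partners)), FALSE)
  }
  regression_problem(Phi, yp, lower, labels, prunable)
}

#' Identify the stage-specific protein-protein interaction network
#'
#' Fits the bilinear interaction model for every protein appearing in the
#' candidate PPI edge set, over the samples of one stage, pruning candidate
#' partners by [prune_by_aic()].  The basal level (and, in full mode, the
#' translation rate) is never pruned.  Because the model is written per
#' target protein, the interaction ability of an unordered pair is
#' estimated independently in each endpoint's regression; the resulting
#' directional coefficients need not agree and are reported as separate
#' edges (`target` = modelled protein, `source` = partner).
#'
#' @inheritParams build_ppin_regression
#' @param dataset An [omics_dataset()].
#' @param candidates A [candidate_gen()].
#' @param stage Canonical stage label (at least 3 samples).
#' @param include_normals Pool normal samples with the stage's samples.
#' @param proteins Proteins to fit (default: every node of the candidate
#'   PPI edge set present in the abundance matrix).
#' @return An [identified_gen()] holding the protein-side network.
#' @export
identify_ppin <- function(dataset, candidates, stage,
                          mode = c("mrna_proxy", "full"),
                          protein_expr = NULL, include_normals = FALSE,
                          proteins = NULL) {
  mode <- match.arg(mode)
  if (mode == "full" && is.null(protein_expr)) {
    protein_expr <- dataset$protein_expr
    if (is.null(protein_expr)) {
      stop_genpnp("Full-protein mode needs a `protein_expr` matrix.", "mode_error")
    }
  }
  samples <- stage_samples(dataset, stage, include_normals)
  if (length(samples) < 3) {
    stop_genpnp(sprintf("Stage '%s' has fewer than 3 samples.", stage),
                "validation_error")
  }
  abundance <- if (mode == "full") protein_expr else dataset$gene_expr
  proteins <- proteins %||% sort(intersect(
    unique(c(candidates$ppi_edges$source, candidates$ppi_edges$target)),
    rownames(abundance)
  ))

  fits <- purrr::map(proteins, function(p) {
    fit <- prune_by_aic(build_ppin_regression(
      p, dataset, candidates, mode = mode,
      protein_expr = protein_expr, samples = samples
    ))
    lab <- tibble(column = fit$selected, coefficient = unname(fit$theta))
    kept <- lab[grepl("^ppi:", lab$column), ]
    edges <- if (nrow(kept)) {
      tibble(source = sub("^ppi:", "", kept$column), target = p,
             edge_type = "ppi", coefficient = kept$coefficient, stage = stage)
    } else NULL
    node <- tibble(
      node = p, role = "protein",
      basal = unname(fit$theta[fit$selected == "basal"]),
      translation = if (mode == "full")
        unname(fit$theta[fit$selected == "translation"]) else NA_real_,
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

#' Identify the complete GEN of one stage
#'
#' Convenience wrapper running [identify_grn()] and [identify_ppin()] on
#' the same stage and merging the two layers.
#'
#' @inheritParams identify_ppin
#' @return An [identified_gen()].
#' @export
identify_gen <- function(dataset, candidates, stage,
                         mode = c("mrna_proxy", "full"),
                         protein_expr = NULL, include_normals = FALSE) {
  merge_identified_gen(
    identify_grn(dataset, candidates, stage, include_normals),
    identify_ppin(dataset, candidates, stage, mode = mode,
                  protein_expr = protein_expr, include_normals = include_normals)
  )
}

#' Flag protein pairs recovered in only one direction
#'
#' The interaction ability of an unordered pair is estimated once per
#' endpoint; this utility reports, for each recovered pair, the two
#' directional coefficients (if any) and whether the pair was recovered
#' from both sides.
#'
#' @param gen An [identified_gen()].
#' @return A tibble with one row per unordered recovered pair.
#' @export
ppi_direction_report <- function(gen) {
  pp <- gen$edges[gen$edges$edge_type == "ppi", ]
  if (nrow(pp) == 0) {
    return(tibble(source = character(0), target = character(0),
                  coef_forward = numeric(0), coef_reverse = numeric(0),
                  bidirectional = logical(0)))
  }
  pp |>
    dplyr::mutate(
      lo = pmin(.data$source, .data$target),
      hi = pmax(.data$source, .data$target),
      dir = ifelse(.data$target == .data$lo, "coef_forward", "coef_reverse")
    ) |>
    dplyr::group_by(.data$lo, .data$hi) |>
    dplyr::summarise(
      coef_forward = .data$coefficient[match("coef_forward", .data$dir)],
      coef_reverse = .data$coefficient[match("coef_reverse", .data$dir)],
      .groups = "drop"
    ) |>
    dplyr::mutate(bidirectional = !is.na(.data$coef_forward) &
                    !is.na(.data$coef_reverse)) |>
    dplyr::rename(source = "lo", target = "hi")
}
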