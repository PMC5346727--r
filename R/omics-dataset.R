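#' Canonicalize tumour-stage labels
#'
#' Stage labels are reduced to `normal`, `I`, `II`, `III`, `IV`.
#' TNM sub-stages are merged into their parent group: `IIIA`, `IIIB` and
#' `IIIC` become `III`; `IVA` and `IVB` become `IV`.  Matching is
#' case-insensitive for `normal`.
#'
#' @param stage Character vector of stage labels.
#' @return Character vector of canonical labels.
#' @export
canonicalize_stage <- function(stage) {
  s <- trimws(as.character(stage))
  s[tolower(s) == "normal"] <- "normal"
  s <- sub("^III[ABC]$", "III", toupper_stage(s))
  s <- sub("^IV[AB]$", "IV", s)
  bad <- !s %in% c("normal", "I", "II", "III", "IV")
  if (any(bad)) {
    stop_genpnp(
      sprintf("Unknown stage label(s): %s",
              paste(unique(stage[bad]), collapse = ", ")),
      "validation_error"
    )
  }
  s
}

toupper_stage <- function(s) ifelse(s == "normal", s, toupper(s))

#' Assemble an aligned multi-omics dataset
#'
#' Bundles a gene-expression matrix, a miRNA-expression matrix and a
#' promoter-methylation matrix measured on the same samples, together with a
#' stage label per sample.  All three matrices must share an identical,
#' identically ordered set of sample columns; methylation values must lie in
#' `[0, 1]`; feature ids must be unique within each matrix; and every sample
#' must carry a stage label.
#'
#' @param gene_expr Numeric matrix, genes x samples (non-negative).
#' @param mirna_expr Numeric matrix, miRNAs x samples (non-negative).
#' @param methylation Numeric matrix, genes x samples, values in `[0, 1]`.
#' @param stages Tibble or data frame with columns `sample` and `stage`, or
#'   a named character vector mapping sample id to stage label.  Labels are
#'   canonicalized with [canonicalize_stage()].
#' @return An object of class `omics_dataset`.
#' @export
omics_dataset <- function(gene_expr, mirna_expr, methylation, stages) {
  gene_expr <- as.matrix(gene_expr)
  mirna_expr <- as.matrix(mirna_expr)
  methylation <- as.matrix(methylation)
  if (is.null(dim(stages)) && !is.null(names(stages))) {
    stages <- tibble(sample = names(stages), stage = unname(stages))
  }
  stages <- as_tibble(stages)[, c("sample", "stage")]
  stages$stage <- canonicalize_stage(stages$stage)

  samples <- colnames(gene_expr)
  for (nm in c("gene_expr", "mirna_expr", "methylation")) {
    m <- get(nm)
    if (is.null(colnames(m)) || is.null(rownames(m))) {
      stop_genpnp(sprintf("`%s` needs row (feature) and column (sample) names.", nm),
                  "validation_error")
    }
    if (anyDuplicated(rownames(m))) {
      stop_genpnp(sprintf("Duplicate feature ids in `%s`.", nm), "validation_error")
    }
    if (!identical(colnames(m), samples)) {
      stop_genpnp(
        sprintf("Sample columns of `%s` do not match `gene_expr` (same ids, same order required).", nm),
        "validation_error"
      )
    }
  }
  if (!identical(rownames(methylation), rownames(gene_expr))) {
    stop_genpnp("`methylation` must have the same gene rows as `gene_expr`.",
                "validation_error")
  }
  bad <- which(methylation < 0 | methylation > 1, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop_genpnp(
      sprintf("Methylation value outside [0, 1]: gene %s, sample %s (value %g).",
              rownames(methylation)[bad[1, 1]], samples[bad[1, 2]],
              methylation[bad[1, , drop = FALSE]]),
      "validation_error"
    )
  }
  missing_lab <- setdiff(samples, stages$sample)
  if (length(missing_lab) > 0) {
    stop_genpnp(sprintf("Samples without a stage label: %s",
                        paste(head(missing_lab, 5), collapse = ", ")),
                "validation_error")
  }
  stages <- stages[match(samples, stages$sample), ]

  structure(
    list(gene_expr = gene_expr, mirna_expr = mirna_expr,
         methylation = methylation, stages = stages),
    class = "omics_dataset"
  )
}

#' @export
print.omics_dataset <- function(x, ...) {
  tab <- table(x$stages$stage)
  cat(sprintf(
    "<omics_dataset> %d genes, %d miRNAs, %d samples (%s)\n",
    nrow(x$gene_expr), nrow(x$mirna_expr), ncol(x$gene_expr),
    paste(sprintf("%s: %d", names(tab), tab), collapse = ", ")
  ))
  invisible(x)
}

#' Number of samples in a dataset
#' @param dataset An [omics_dataset()].
#' @return Integer sample count.
#' @export
n_samples <- function(dataset) ncol(dataset$gene_expr)

#' Sample ids belonging to a stage
#'
#' @param dataset An [omics_dataset()].
#' @param stage Canonical stage label.
#' @param include_normals Also include the normal samples (used when a
#'   stage-specific network is fitted on tumour plus normal profiles).
#' @return Character vector of sample ids.
#' @export
stage_samples <- function(dataset, stage, include_normals = FALSE) {
  stage <- canonicalize_stage(stage)
  if (!stage %in% dataset$stages$stage) {
    stop_genpnp(sprintf("Stage '%s' has no samples in this dataset.", stage),
                "validation_error")
  }
  want <- dataset$stages$stage == stage
  if (include_normals) want <- want | dataset$stages$stage == "normal"
  dataset$stages$sample[want]
}

#' Restrict a dataset to a subset of samples
#' @param dataset An [omics_dataset()].
#' @param samples Character vector of sample ids (kept in the given order).
#' @return An [omics_dataset()].
#' @export
subset_samples <- function(dataset, samples) {
  omics_dataset(
    dataset$gene_expr[, samples, drop = FALSE],
    dataset$mirna_expr[, samples, drop = FALSE],
    dataset$methylation[, samples, drop = FALSE],
    dataset$stages[dataset$stages$sample %in% samples, ]
  )
}

# ---- on-disk representation ------------------------------------------------

read_matrix_tsv <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (ncol(df) < 2) {
    stop_genpnp(sprintf("Matrix file '%s' needs an id column and at least one sample.", path),
                "load_error")
  }
  m <- as.matrix(df[, -1])
  rownames(m) <- as.character(df[[1]])
  storage.mode(m) <- "double"
  m
}

write_matrix_tsv <- function(m, path) {
  df <- tibble::as_tibble(m, rownames = "id")
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}

#' Read an aligned multi-omics dataset from TSV files
#'
#' Each matrix file is tab-separated with a header row of sample ids and a
#' first column of feature ids (header `id`).  The three matrices are
#' column-aligned on the intersection of their sample ids, ordered as in the
#' expression file; samples missing from any file are dropped with a
#' warning.  The label file maps sample ids to stage labels (columns
#' `sample`, `stage`, or the first two columns).
#'
#' @param expr_path,mirna_path,meth_path,labels_path Paths to the gene
#'   expression, miRNA expression, methylation and stage-label TSV files.
#' @return An [omics_dataset()].
#' @export
read_omics_dataset <- function(expr_path, mirna_path, meth_path, labels_path) {
  gene_expr <- read_matrix_tsv(expr_path)
  mirna_expr <- read_matrix_tsv(mirna_path)
  methylation <- read_matrix_tsv(meth_path)

  common <- intersect(
    intersect(colnames(gene_expr), colnames(mirna_expr)),
    colnames(methylation)
  )
  common <- colnames(gene_expr)[colnames(gene_expr) %in% common]
  if (length(common) == 0) {
    stop_genpnp(
      sprintf("No sample ids shared by '%s', '%s' and '%s'.",
              expr_path, mirna_path, meth_path),
      "load_error"
    )
  }
  dropped <- unique(c(
    setdiff(colnames(gene_expr), common),
    setdiff(colnames(mirna_expr), common),
    setdiff(colnames(methylation), common)
  ))
  if (length(dropped) > 0) {
    warn_genpnp(
      sprintf("%d sample(s) not present in all omics files were dropped: %s",
              length(dropped), paste(head(dropped, 5), collapse = ", ")),
      "alignment_warning"
    )
  }

  labels <- readr::read_tsv(labels_path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("sample", "stage") %in% names(labels))) {
    names(labels)[1:2] <- c("sample", "stage")
  }
  labels$sample <- as.character(labels$sample)

  omics_dataset(
    gene_expr[, common, drop = FALSE],
    mirna_expr[, common, drop = FALSE],
    methylation[, common, drop = FALSE],
    labels
  )
}

#' Write an omics dataset as TSV files
#'
#' Emits `gene_expr.tsv`, `mirna_expr.tsv`, `methylation.tsv` and
#' `stages.tsv` under `dir`.
#'
#' @param dataset An [omics_dataset()].
#' @param dir Output directory (created if missing).
#' @return The paths of the four files, invisibly.
#' @export
write_omics_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, c("gene_expr.tsv", "mirna_expr.tsv",
                            "methylation.tsv", "stages.tsv"))
  write_matrix_tsv(dataset$gene_expr, paths[1])
  write_matrix_tsv(dataset$mirna_expr, paths[2])
  write_matrix_tsv(dataset$methylation, paths[3])
  readr::write_tsv(dataset$stages, paths[4], progress = FALSE)
  invisible(paths)
}
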