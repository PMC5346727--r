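#' Run the full GEN construction pipeline
#'
#' Ties the stages together: per tumour stage, identify the transcriptional
#' and protein layers, merge them into one network, assemble the combined
#' network matrix, decompose it by principal network projection and extract
#' the core; then compare adjacent stages (edge polarity, projection
#' distance correlation, core set differences, differential methylation and
#' miRNA calls) and optionally select target-specific drugs.  All outputs
#' are written as TSV under the run directory together with a JSON manifest
#' (configuration hash, seed, package version and a content hash per
#' artifact) so that a rerun can be verified bitwise.
#'
#' The configuration is a nested list (or the path of a YAML file) with
#' blocks:
#' \describe{
#'   \item{seed}{integer; every stochastic step derives from it.}
#'   \item{simulate}{[generator_config()] overrides; if present the run is
#'     simulation-based and a parameter-recovery report is produced.}
#'   \item{input}{alternatively, paths `expr`, `mirna`, `meth`, `labels`,
#'     `tf_edges`, `mirna_edges`, `ppi_edges`.}
#'   \item{stages}{stages to fit (default I--IV).}
#'   \item{include_normals, ppin_mode}{identification options.}
#'   \item{pnp}{`energy`, selection `mode` (`top`/`threshold`) and
#'     `top_proteins`/`top_genes`/`top_mirnas` or `th1`/`th2`/`th3`.}
#'   \item{compare}{`alpha`, `min_delta`.}
#'   \item{drugs}{`table` (TSV path), `targets`, optional
#'     `network_genes`.}
#' }
#'
#' @param config Nested list or YAML file path.
#' @param out_dir Run directory (default: `config$out_dir` or
#'   `"genpnp_run"`).
#' @return Invisibly, a list with the identified networks, decompositions,
#'   cores, comparison tables, the recovery report (simulation runs) and
#'   the manifest.
#' @export
run_pipeline <- function(config = list(), out_dir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  defaults <- list(
    seed = 1L, out_dir = "genpnp_run",
    stages = c("I", "II", "III", "IV"),
    include_normals = FALSE, ppin_mode = "mrna_proxy",
    pnp = list(energy = 0.85, mode = "top",
               top_proteins = 30, top_genes = 30, top_mirnas = 15,
               th1 = NULL, th2 = NULL, th3 = NULL),
    compare = list(alpha = 0.05, min_delta = 0.1),
    simulate = NULL, input = NULL, drugs = NULL
  )
  cfg <- utils::modifyList(defaults, config)
  out_dir <- out_dir %||% cfg$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  run_step <- function(stage_name, expr) {
    tryCatch(expr, error = function(e) {
      stop_genpnp(sprintf("Pipeline failed in step '%s': %s",
                          stage_name, conditionMessage(e)),
                  "pipeline_error")
    })
  }

  # ---- inputs ----
  truth <- NULL; candidates <- NULL
  if (!is.null(cfg$simulate)) {
    gencfg <- run_step("simulate", do.call(
      generator_config,
      utils::modifyList(list(seed = cfg$seed), cfg$simulate)
    ))
    truth <- generate_truth(gencfg)
    dataset <- simulate_dataset(truth)
    candidates <- corrupt_candidates(truth, seed = gencfg$seed + 777L)
    genes <- truth$roles$genes; mirnas <- truth$roles$mirnas
  } else if (!is.null(cfg$input)) {
    dataset <- run_step("load", read_omics_dataset(
      cfg$input$expr, cfg$input$mirna, cfg$input$meth, cfg$input$labels))
    candidates <- run_step("load", read_candidate_gen(
      cfg$input$tf_edges, cfg$input$mirna_edges, cfg$input$ppi_edges))
    genes <- rownames(dataset$gene_expr)
    mirnas <- rownames(dataset$mirna_expr)
  } else {
    stop_genpnp("Config needs either a `simulate` or an `input` block.",
                "config_error")
  }

  # ---- per-stage identification, PNP, core ----
  gens <- list(); pnps <- list(); cores <- list(); recovery <- list()
  for (stage in cfg$stages) {
    gen <- run_step(paste0("identify:", stage), identify_gen(
      dataset, candidates, stage, mode = cfg$ppin_mode,
      include_normals = cfg$include_normals))
    write_identified_gen(gen, file.path(out_dir, sprintf("gen_%s.tsv", stage)))
    nm <- run_step(paste0("assemble:", stage),
                   assemble_network_matrix(gen, genes, mirnas))
    pnp <- run_step(paste0("pnp:", stage), pnp_decompose(nm, cfg$pnp$energy))
    readr::write_tsv(pnp$distances,
                     file.path(out_dir, sprintf("distances_%s.tsv", stage)),
                     progress = FALSE)
    core <- run_step(paste0("core:", stage), if (cfg$pnp$mode == "threshold") {
      extract_core(pnp, mode = "threshold",
                   thresholds = c(protein = cfg$pnp$th1, gene = cfg$pnp$th2,
                                  mirna = cfg$pnp$th3), gen = gen)
    } else {
      extract_core(pnp, mode = "top",
                   top_counts = c(protein = cfg$pnp$top_proteins,
                                  gene = cfg$pnp$top_genes,
                                  mirna = cfg$pnp$top_mirnas), gen = gen)
    })
    readr::write_tsv(core$nodes,
                     file.path(out_dir, sprintf("core_%s.tsv", stage)),
                     progress = FALSE)
    readr::write_tsv(core$edges,
                     file.path(out_dir, sprintf("core_edges_%s.tsv", stage)),
                     progress = FALSE)
    gens[[stage]] <- gen; pnps[[stage]] <- pnp; cores[[stage]] <- core
    if (!is.null(truth)) {
      recovery[[stage]] <- dplyr::mutate(
        score_recovery(truth, gen, candidates), stage = stage, .before = 1)
    }
  }
  if (length(recovery)) {
    readr::write_tsv(dplyr::bind_rows(recovery),
                     file.path(out_dir, "recovery.tsv"), progress = FALSE)
  }

  # ---- adjacent-stage comparisons ----
  comparisons <- list()
  if (length(cfg$stages) >= 2) {
    for (i in seq_len(length(cfg$stages) - 1)) {
      a <- cfg$stages[i]; b <- cfg$stages[i + 1]
      tag <- sprintf("%s_vs_%s", a, b)
      pol <- polarity_consistency(gens[[a]], gens[[b]])
      r2 <- projection_distance_r2(pnps[[a]], pnps[[b]])
      diff_meth <- run_step(paste0("compare:", tag), differential_methylation(
        dataset, a, b, alpha = cfg$compare$alpha,
        min_delta = cfg$compare$min_delta))
      diff_mir <- differential_mirna(dataset, a, b, alpha = cfg$compare$alpha)
      core_diff <- compare_core_gens(cores[[a]], cores[[b]])
      readr::write_tsv(diff_meth,
                       file.path(out_dir, sprintf("diff_methylation_%s.tsv", tag)),
                       progress = FALSE)
      readr::write_tsv(diff_mir,
                       file.path(out_dir, sprintf("diff_mirna_%s.tsv", tag)),
                       progress = FALSE)
      readr::write_tsv(core_diff$nodes,
                       file.path(out_dir, sprintf("core_diff_%s.tsv", tag)),
                       progress = FALSE)
      comparisons[[tag]] <- tibble(
        stage_a = a, stage_b = b,
        polarity_consistency = pol$consistency, shared_edges = pol$n_shared,
        distance_r2 = r2$r2,
        n_diff_methylated = sum(diff_meth$called, na.rm = TRUE),
        n_diff_mirna = sum(diff_mir$called, na.rm = TRUE)
      )
    }
    readr::write_tsv(dplyr::bind_rows(comparisons),
                     file.path(out_dir, "comparisons.tsv"), progress = FALSE)
  }

  # ---- drug selection ----
  drug_report <- NULL
  if (!is.null(cfg$drugs)) {
    tab <- if (is.character(cfg$drugs$table)) read_drug_gene_table(cfg$drugs$table)
           else as_tibble(cfg$drugs$table)
    network_genes <- cfg$drugs$network_genes %||% unique(unlist(
      lapply(cores, function(co) co$nodes$node[co$nodes$role != "mirna"])))
    sel <- run_step("drugs", select_specific_drugs(
      tab, cfg$drugs$targets, union(network_genes, cfg$drugs$targets)))
    drug_report <- multi_drug_report(sel, targets = cfg$drugs$targets)
    readr::write_tsv(sel, file.path(out_dir, "drug_candidates.tsv"),
                     progress = FALSE)
    readr::write_tsv(drug_report, file.path(out_dir, "multi_drug_report.tsv"),
                     progress = FALSE)
  }

  # ---- manifest ----
  files <- sort(setdiff(list.files(out_dir), "manifest.json"))
  manifest <- list(
    package = "genpnp",
    version = as.character(utils::packageVersion("genpnp")),
    seed = cfg$seed,
    config_hash = rlang::hash(cfg),
    files = lapply(setNames(files, files), function(f)
      rlang::hash_file(file.path(out_dir, f))[[1]])
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  invisible(list(
    dataset = dataset, candidates = candidates, truth = truth,
    gens = gens, pnps = pnps, cores = cores,
    comparisons = if (length(comparisons)) dplyr::bind_rows(comparisons) else NULL,
    recovery = if (length(recovery)) dplyr::bind_rows(recovery) else NULL,
    drug_report = drug_report, manifest = manifest, out_dir = out_dir
  ))
}
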