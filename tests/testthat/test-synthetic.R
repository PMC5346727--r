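test_that("identical configuration and seed reproduce bitwise-identical data", {
  cfg <- generator_config(seed = 11)
  t1 <- generate_truth(cfg); t2 <- generate_truth(cfg)
  expect_identical(t1, t2)
  d1 <- simulate_stage(t1, "II", L = 40, seed = 5)
  d2 <- simulate_stage(t2, "II", L = 40, seed = 5)
  expect_identical(d1, d2)
  c1 <- corrupt_candidates(t1, seed = 3); c2 <- corrupt_candidates(t2, seed = 3)
  expect_identical(c1, c2)
})

test_that("zero edge densities give empty edge sets with basal levels only", {
  cfg <- generator_config(tf_per_gene = 0, mirna_per_gene = 0,
                          partners_per_protein = 0, seed = 2)
  tr <- generate_truth(cfg)
  expect_equal(nrow(tr$tf_edges), 0)
  expect_equal(nrow(tr$mirna_edges), 0)
  expect_equal(nrow(tr$ppi_pairs), 0)
  expect_true(all(tr$k$k > 0))
})

test_that("candidate counts concentrate around the configured density", {
  counts <- unlist(lapply(1:300, function(s) {
    tr <- generate_truth(generator_config(tf_per_gene = 3, seed = s))
    tabulate(factor(tr$tf_edges$target, levels = tr$roles$regulated))
  }))
  expect_equal(mean(counts), 3, tolerance = 0.05)
})

test_that("generated parameters respect their sign and range constraints", {
  tr <- fixture_truth(7)
  expect_true(all(abs(tr$tf_edges$a) >= 0.3 & abs(tr$tf_edges$a) <= 1))
  expect_true(all(tr$mirna_edges$b >= 0.1 & tr$mirna_edges$b <= 0.5))
  expect_true(all(abs(tr$ppi_pairs$c) >= 0.02 & abs(tr$ppi_pairs$c) <= 0.1))
  expect_true(all(tr$k$k >= 0) && all(tr$h$h >= 0))
  expect_true(all(tr$meth_means >= 0 & tr$meth_means <= 1))
})

test_that("noise-free data satisfy both structural equations exactly", {
  tr <- fixture_truth(5, sigma_v = 0, sigma_w = 0)
  ds <- simulate_stage(tr, "III", L = 25, seed = 8)
  hb <- methylation_attenuation(ds$methylation)
  for (g in tr$roles$regulated) {
    tfe <- tr$tf_edges[tr$tf_edges$target == g, ]
    mie <- tr$mirna_edges[tr$mirna_edges$target == g, ]
    k <- tr$k$k[tr$k$gene == g]
    act <- if (nrow(tfe)) colSums(ds$gene_expr[tfe$source, , drop = FALSE] * tfe$a) else 0
    rep_load <- if (nrow(mie)) colSums(ds$mirna_expr[mie$source, , drop = FALSE] * mie$b) else 0
    lhs <- ds$gene_expr[g, ] * (1 + rep_load)
    rhs <- (act + k) * hb[g, ]
    expect_lt(max(abs(lhs - rhs)), 1e-10)
  }
  terms <- genpnp:::ppi_terms(tr)
  for (p in tr$roles$responsive) {
    tm <- terms[terms$protein == p, ]
    h <- tr$h$h[tr$h$protein == p]
    y <- ds$gene_expr[p, ]
    rhs <- colSums(ds$gene_expr[tm$partner, , drop = FALSE] * tm$c) * y + h
    expect_lt(max(abs(y - rhs)), 1e-9)
  }
})

test_that("a lone repressed gene solves the transcription balance in closed form", {
  # one gene, one miRNA with b = 0.5 and s = 1, no TFs, beta = 0, k = 2:
  # the balance x (1 + 0.5) = 2 gives x = 4/3 exactly
  cfg <- generator_config(n_genes = 1, n_tfs = 0, n_proteins = 0, n_mirnas = 1,
                          tf_per_gene = 0, mirna_per_gene = 1,
                          partners_per_protein = 0, mirna_sdlog = 0,
                          mirna_shift_frac = 0, sigma_v = 0, sigma_w = 0,
                          meth_concentration = Inf, seed = 4)
  tr <- generate_truth(cfg)
  tr$mirna_edges <- tibble::tibble(source = "MIR01", target = "G01", b = 0.5)
  tr$k <- tibble::tibble(gene = "G01", k = 2)
  tr$meth_means[, ] <- 0
  ds <- simulate_stage(tr, "I", L = 5, seed = 1)
  expect_equal(unname(ds$gene_expr["G01", ]), rep(4 / 3, 5))
})

test_that("a gene without regulators at beta 0 expresses its basal level", {
  cfg <- generator_config(n_genes = 1, n_tfs = 0, n_proteins = 0, n_mirnas = 1,
                          tf_per_gene = 0, mirna_per_gene = 0,
                          partners_per_protein = 0, sigma_v = 0, sigma_w = 0,
                          meth_concentration = Inf, seed = 4)
  tr <- generate_truth(cfg)
  tr$meth_means[, ] <- 0
  ds <- simulate_stage(tr, "I", L = 3, seed = 2)
  expect_equal(unname(ds$gene_expr["G01", ]),
               rep(tr$k$k, 3))
})

test_that("methylation values stay inside the unit interval across stages", {
  tr <- fixture_truth(9)
  for (st in c("normal", "I", "IV")) {
    ds <- simulate_stage(tr, st, L = 30, seed = 6)
    expect_true(all(ds$methylation >= 0 & ds$methylation <= 1))
    expect_true(all(ds$gene_expr > 0))
    expect_true(all(ds$mirna_expr > 0))
  }
})

test_that("candidate corruption adds the configured decoy fraction and no duplicates", {
  tr <- fixture_truth(3)
  ca0 <- corrupt_candidates(tr, rho = 0, seed = 1)
  expect_equal(nrow(ca0$tf_edges), nrow(tr$tf_edges))
  expect_equal(nrow(ca0$ppi_edges), nrow(tr$ppi_pairs))

  ca <- corrupt_candidates(tr, rho = 0.5, seed = 1)
  dec <- attr(ca, "decoys")
  expect_equal(nrow(dec$tf), nrow(tr$tf_edges))      # rho = 0.5: one decoy per true edge
  expect_equal(nrow(dec$mirna), nrow(tr$mirna_edges))
  # decoys never duplicate true edges
  expect_equal(nrow(dplyr::semi_join(dec$tf, tr$tf_edges,
                                     by = c("source", "target"))), 0)
  expect_equal(nrow(dplyr::semi_join(dec$ppi, tr$ppi_pairs,
                                     by = c("source", "target"))), 0)
  expect_error(corrupt_candidates(tr, rho = 1), class = "genpnp_config_error")
})

test_that("recovery scoring handles the trivial and degenerate cases", {
  tr <- fixture_truth(6)
  perfect <- truth_as_identified(tr)
  sc <- score_recovery(tr, perfect)
  expect_equal(sc$precision, 1); expect_equal(sc$recall, 1)
  expect_equal(sc$sign_accuracy, 1); expect_equal(sc$coef_rmse, 0)
  expect_equal(sc$node_exact_fraction, 1)

  empty <- identified_gen(perfect$edges[0, ], perfect$nodes, "I")
  sc0 <- score_recovery(tr, empty)
  expect_equal(sc0$recall, 0)
  expect_equal(sc0$precision, 1)          # undefined-by-convention
  expect_false(sc0$precision_defined)

  # one flipped sign among the TF edges
  flipped <- perfect
  i <- which(flipped$edges$edge_type == "tf")[1]
  flipped$edges$coefficient[i] <- -flipped$edges$coefficient[i]
  n_dir <- nrow(truth_edges(tr))
  expect_equal(score_recovery(tr, flipped)$sign_accuracy, (n_dir - 1) / n_dir)

  # disjoint universes are an error
  alien <- identified_gen(
    tibble::tibble(source = "X1", target = "X2", edge_type = "tf",
                   coefficient = 1, stage = "I"),
    tibble::tibble(node = "X2", role = "gene", basal = 0,
                   translation = NA_real_, sse = 0, aic = 0, order = 1L), "I")
  expect_error(score_recovery(tr, alien), class = "genpnp_validation_error")
})

test_that("configuration errors are caught early", {
  expect_error(generator_config(tf_per_gene = 50), class = "genpnp_config_error")
  expect_error(generator_config(rho = 1), class = "genpnp_config_error")
  expect_error(generator_config(n_tfs = 25, n_proteins = 20),
               class = "genpnp_config_error")
})

test_that("full-protein simulation satisfies the translation-bearing model", {
  tr <- fixture_truth(8, sigma_v = 0, sigma_w = 0)
  ds <- simulate_stage(tr, "I", L = 20, seed = 3, protein_mode = "full")
  expect_true(!is.null(ds$protein_expr))
  terms <- genpnp:::ppi_terms(tr)
  for (p in tr$roles$responsive[1:3]) {
    tm <- terms[terms$protein == p, ]
    h <- tr$config$full_h_scale * tr$h$h[tr$h$protein == p]
    e <- tr$e$e[tr$e$protein == p]
    y <- ds$protein_expr[p, ]
    rhs <- colSums(ds$protein_expr[tm$partner, , drop = FALSE] * tm$c) * y +
      e * ds$gene_expr[p, ] + h
    expect_lt(max(abs(y - rhs)), 1e-9)
  }
})
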