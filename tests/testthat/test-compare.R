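two_stage_dataset <- function(beta_a, beta_b, mirna_a = 1, mirna_b = 1,
                              n = 20, seed = 1) {
  withr::with_seed(seed, {
    samples <- paste0("S", seq_len(2 * n))
    genes <- "G1"
    ge <- matrix(rlnorm(2 * n), 1, 2 * n, dimnames = list(genes, samples))
    mi <- matrix(c(rlnorm(n, log(mirna_a), 0.1), rlnorm(n, log(mirna_b), 0.1)),
                 1, 2 * n, dimnames = list("M1", samples))
    me <- matrix(pmin(pmax(c(rnorm(n, beta_a, 0.05), rnorm(n, beta_b, 0.05)),
                           0), 1),
                 1, 2 * n, dimnames = list(genes, samples))
    tiny_dataset(ge, mi, me, rep(c("I", "II"), each = n))
  })
}

test_that("differential methylation needs both significance and effect size", {
  same <- two_stage_dataset(0.3, 0.3)
  expect_false(differential_methylation(same, "I", "II")$called)

  up <- differential_methylation(two_stage_dataset(0.3, 0.6), "I", "II")
  expect_true(up$called)
  expect_identical(up$direction, "hyper")
  expect_lt(up$p, 0.05)

  down <- differential_methylation(two_stage_dataset(0.6, 0.3), "I", "II")
  expect_identical(down$direction, "hypo")

  # a tiny but significant shift is below the effect-size floor
  small <- differential_methylation(two_stage_dataset(0.30, 0.35, n = 200),
                                    "I", "II")
  expect_lt(small$p, 0.05)
  expect_false(small$called)

  # absent genes are reported untested
  res <- differential_methylation(two_stage_dataset(0.3, 0.6), "I", "II",
                                  genes = c("G1", "GX"))
  expect_false(res$tested[res$gene == "GX"])
})

test_that("differential miRNA calls carry the direction of change", {
  expect_false(differential_mirna(two_stage_dataset(0.3, 0.3), "I", "II")$called)
  up <- differential_mirna(two_stage_dataset(0.3, 0.3, mirna_a = 1, mirna_b = 2),
                           "I", "II")
  expect_true(up$called); expect_identical(up$direction, "up")
  down <- differential_mirna(two_stage_dataset(0.3, 0.3, mirna_a = 2, mirna_b = 1),
                             "I", "II")
  expect_identical(down$direction, "down")
})

make_gen <- function(coefs, stage = "I") {
  edges <- tibble::tibble(
    source = paste0("TF", seq_along(coefs)), target = "G1",
    edge_type = "tf", coefficient = coefs, stage = stage)
  identified_gen(edges, tibble::tibble(
    node = "G1", role = "gene", basal = 1, translation = NA_real_,
    sse = 0, aic = 0, order = length(coefs)), stage)
}

test_that("polarity consistency counts shared-edge sign agreement", {
  g <- make_gen(c(0.5, -0.3, 0.2, 0.1, -0.4, 0.6))
  self <- polarity_consistency(g, g)
  expect_equal(self$consistency, 1)

  flipped <- make_gen(-c(0.5, -0.3, 0.2, 0.1, -0.4, 0.6), stage = "II")
  expect_equal(polarity_consistency(g, flipped)$consistency, 0)

  half <- make_gen(c(0.5, -0.3, 0.2, -0.1, 0.4, -0.6), stage = "II")
  res <- polarity_consistency(g, half)
  expect_equal(res$consistency, 0.5)
  expect_equal(res$n_shared, 6)
  expect_equal(res$n_sign_changed, 3)

  # symmetry in the arguments
  expect_equal(polarity_consistency(half, g)$consistency, 0.5)

  # disjoint edge sets: undefined, flagged
  other <- identified_gen(
    tibble::tibble(source = "TFX", target = "GX", edge_type = "tf",
                   coefficient = 1, stage = "II"),
    tibble::tibble(node = "GX", role = "gene", basal = 0,
                   translation = NA_real_, sse = 0, aic = 0, order = 1L), "II")
  none <- polarity_consistency(g, other)
  expect_false(none$defined)
  expect_true(is.na(none$consistency))
})

test_that("projection-distance R2 is exact for affine relations", {
  dist_tbl <- function(d) tibble::tibble(
    node = paste0("N", seq_along(d)), role = "gene", distance = d)
  d <- withr::with_seed(2, runif(50, 0, 4))
  expect_equal(projection_distance_r2(dist_tbl(d), dist_tbl(d))$r2, 1)
  expect_equal(projection_distance_r2(dist_tbl(d), dist_tbl(2 * d + 3))$r2, 1)
  # constant reference distances leave the regression undefined
  flat <- projection_distance_r2(dist_tbl(rep(1, 50)), dist_tbl(d))
  expect_false(flat$defined)
  expect_error(projection_distance_r2(dist_tbl(d[1:2]), dist_tbl(d[1:2])),
               class = "genpnp_validation_error")
})

test_that("noise equal to the signal halves the explained variance", {
  r2 <- vapply(1:60, function(seed) {
    withr::with_seed(seed, {
      d <- runif(200, 0, 4)
      noisy <- d + rnorm(200, 0, sd(d))
      projection_distance_r2(
        tibble::tibble(node = paste0("N", 1:200), role = "gene", distance = d),
        tibble::tibble(node = paste0("N", 1:200), role = "gene", distance = noisy)
      )$r2
    })
  }, numeric(1))
  expect_equal(mean(r2), 0.5, tolerance = 0.05)
})

test_that("core-set comparison reports shared and specific features exactly", {
  core <- function(nodes, edges = NULL) {
    structure(list(
      nodes = tibble::tibble(node = nodes, role = "gene",
                             distance = 1, rank = seq_along(nodes)),
      edges = edges %||% tibble::tibble(source = character(0),
                                        target = character(0),
                                        edge_type = character(0)),
      mode = "top", params = NULL), class = "core_gen")
  }
  same <- compare_core_gens(core(c("A", "B")), core(c("A", "B")))
  expect_setequal(same$nodes$status, "shared")

  disjoint <- compare_core_gens(core("A"), core("B"))
  expect_false("shared" %in% disjoint$nodes$status)

  e1 <- tibble::tibble(source = c("A", "B"), target = c("B", "C"),
                       edge_type = "tf")
  e2 <- e1[1, ]
  delta <- compare_core_gens(core(c("A", "B", "C"), e1), core(c("A", "B"), e2))
  expect_equal(sum(delta$edges$status == "a_only"), 1)
  expect_equal(sum(delta$edges$status == "shared"), 1)
})

test_that("the enrichment filter keeps rows passing both inclusive rules", {
  tab <- tibble::tibble(
    term = c("MAPK signaling pathway", "X", "Y"),
    count = c(12, 4, 5),
    p = c(9.0e-3, 1e-6, 0.05))
  kept <- filter_enrichment_table(tab)
  expect_setequal(kept$term, c("MAPK signaling pathway", "Y"))
  expect_error(filter_enrichment_table(tibble::tibble(a = 1)),
               class = "genpnp_format_error")
})

test_that("differential calls do not depend on sample order", {
  ds <- two_stage_dataset(0.3, 0.55)
  perm <- withr::with_seed(3, sample(colnames(ds$gene_expr)))
  dsp <- subset_samples(ds, perm)
  expect_equal(differential_methylation(ds, "I", "II"),
               differential_methylation(dsp, "I", "II"))
})
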