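ppin_fixture <- function() {
  samples <- c("S1", "S2")
  ge <- matrix(c(2, 3, 10, 4, 5, 12), 3, 2,
               dimnames = list(c("P1", "P2", "P3"), samples))
  mi <- matrix(1, 1, 2, dimnames = list("M1", samples))
  me <- matrix(0, 3, 2, dimnames = list(c("P1", "P2", "P3"), samples))
  tiny_dataset(ge, mi, me, c("I", "I"))
}

test_that("the proxy-mode regression is bilinear with a free basal column", {
  ds <- ppin_fixture()
  ca <- candidate_gen(ppi_edges = tibble::tibble(source = "P1", target = "P2"))
  pr <- build_ppin_regression("P1", ds, ca)
  expect_identical(colnames(pr$Phi), c("ppi:P2", "basal"))
  # regressor is partner * target abundance per sample
  expect_equal(unname(pr$Phi[, "ppi:P2"]), c(3 * 2, 5 * 4))
  expect_equal(unname(pr$Phi[, "basal"]), c(1, 1))
  expect_equal(pr$lower, c(-Inf, 0))
  # no translation column in proxy mode
  expect_false("translation" %in% pr$labels$role)
})

test_that("full mode adds a non-prunable translation column", {
  ds <- ppin_fixture()
  prot <- ds$gene_expr * 2          # stand-in protein abundances
  ca <- candidate_gen(ppi_edges = tibble::tibble(source = "P1", target = "P2"))
  pr <- build_ppin_regression("P1", ds, ca, mode = "full", protein_expr = prot)
  expect_identical(colnames(pr$Phi), c("ppi:P2", "translation", "basal"))
  expect_equal(unname(pr$Phi[, "translation"]), unname(ds$gene_expr["P1", ]))
  expect_false(pr$prunable[2])
  expect_error(build_ppin_regression("P1", ds, ca, mode = "full"),
               class = "genpnp_mode_error")
})

test_that("a protein never appears as its own partner", {
  ds <- ppin_fixture()
  ca <- suppressWarnings(candidate_gen(
    ppi_edges = tibble::tibble(source = c("P1", "P1"), target = c("P1", "P2"))))
  pr <- build_ppin_regression("P1", ds, ca)
  expect_identical(pr$labels$regulator[pr$labels$role == "ppi"], "P2")
})

test_that("noise-free proxy data yield exact partner recovery", {
  tr <- fixture_truth(3, sigma_v = 0, sigma_w = 0)
  ds <- simulate_stage(tr, "I", seed = 31)
  ca <- corrupt_candidates(tr, seed = 32)
  fit <- identify_ppin(ds, ca, "I")
  sc <- score_recovery(tr, fit, ca)
  expect_equal(sc$ppi_precision, 1)
  expect_equal(sc$ppi_recall, 1)
  # no translation coefficients in proxy mode, basal never negative
  expect_true(all(is.na(fit$nodes$translation)))
  expect_true(all(fit$nodes$basal >= 0))
})

test_that("full-protein mode identifies interaction, translation and basal terms", {
  tr <- fixture_truth(5, sigma_v = 0, sigma_w = 0)
  ds <- simulate_stage(tr, "I", seed = 41, protein_mode = "full")
  ca <- corrupt_candidates(tr, rho = 0, seed = 42)
  fit <- identify_ppin(ds, ca, "I", mode = "full")
  resp <- fit$nodes[fit$nodes$node %in% tr$roles$responsive, ]
  expect_equal(resp$translation,
               tr$e$e[match(resp$node, tr$e$protein)], tolerance = 1e-6)
  expect_equal(resp$basal,
               tr$config$full_h_scale * tr$h$h[match(resp$node, tr$h$protein)],
               tolerance = 1e-6)
  ed <- fit$edges[fit$edges$target %in% tr$roles$responsive, ]
  terms <- genpnp:::ppi_terms(tr)
  m <- dplyr::inner_join(ed, terms,
                         by = c(target = "protein", source = "partner"))
  expect_equal(nrow(m), nrow(terms))
  expect_equal(m$coefficient, m$c, tolerance = 1e-6)
})

test_that("a partnerless protein fits basal only with the residual variance", {
  samples <- paste0("S", 1:8)
  y <- c(5.2, 4.8, 5.1, 5.0, 4.9, 5.3, 4.7, 5.0)
  ge <- matrix(y, 1, 8, dimnames = list("P1", samples))
  mi <- matrix(1, 1, 8, dimnames = list("M1", samples))
  me <- matrix(0, 1, 8, dimnames = list("P1", samples))
  ds <- tiny_dataset(ge, mi, me, rep("I", 8))
  ca <- candidate_gen()
  fit <- identify_ppin(ds, ca, "I", proteins = "P1")
  expect_equal(fit$nodes$basal, mean(y))
  expect_equal(fit$nodes$sse, sum((y - mean(y))^2))
  expect_equal(fit$nodes$order, 0L)
})

test_that("repeated runs on the same data give identical fits", {
  tr <- fixture_truth(6)
  ds <- simulate_stage(tr, "II", L = 80, seed = 51)
  ca <- corrupt_candidates(tr, seed = 52)
  f1 <- identify_ppin(ds, ca, "II")
  f2 <- identify_ppin(ds, ca, "II")
  expect_identical(f1, f2)
})

test_that("one-directional recoveries are flagged by the direction report", {
  gen <- identified_gen(
    edges = tibble::tibble(
      source = c("P2", "P1", "P3"), target = c("P1", "P2", "P1"),
      edge_type = "ppi", coefficient = c(0.05, 0.06, -0.03), stage = "I"),
    nodes = tibble::tibble(node = c("P1", "P2", "P3"), role = "protein",
                           basal = 1, translation = NA_real_, sse = 0,
                           aic = 0, order = 1L),
    stage = "I")
  rep <- ppi_direction_report(gen)
  expect_equal(nrow(rep), 2)
  expect_true(rep$bidirectional[rep$source == "P1" & rep$target == "P2"])
  expect_false(rep$bidirectional[rep$source == "P1" & rep$target == "P3"])
})
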