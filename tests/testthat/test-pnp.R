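toy_gen <- function(edges) {
  identified_gen(
    edges,
    tibble::tibble(node = unique(c(edges$source, edges$target)), role = "gene",
                   basal = 0, translation = NA_real_, sse = 0, aic = 0,
                   order = 1L),
    stage = "I")
}

test_that("coefficients land in the documented blocks of H", {
  genes <- c("G1", "G2"); mirnas <- "M1"
  gen <- toy_gen(tibble::tibble(
    source = c("G1", "M1"), target = c("G2", "G1"),
    edge_type = c("tf", "mirna"), coefficient = c(0.7, -0.5), stage = "I"))
  nm <- assemble_network_matrix(gen, genes, mirnas)
  expect_equal(dim(nm$H), c(5, 2))
  expect_equal(nm$H[3, 2], 0.7)                      # TF block row N + j
  expect_equal(nm$H[5, 1], -0.5)                     # miRNA block row 2N + m
  expect_equal(sum(nm$H != 0), 2)
  # protein block
  gen2 <- toy_gen(tibble::tibble(source = "G2", target = "G1",
                                 edge_type = "ppi", coefficient = 0.05,
                                 stage = "I"))
  nm2 <- assemble_network_matrix(gen2, genes, mirnas)
  expect_equal(nm2$H[2, 1], 0.05)
  # the miRNA block is never positive
  expect_true(all(nm$H[5, ] <= 0))
  # out-of-universe nodes are an assembly error
  expect_error(assemble_network_matrix(gen, "G1", mirnas),
               class = "genpnp_assembly_error")
})

test_that("eigenexpression fractions and the minimal energy rule are exact", {
  H <- diag(c(3, 1))                                  # singular values 3, 1
  res <- pnp_decompose(H, energy = 0.85)
  expect_equal(res$energy_fraction, c(0.9, 0.1))
  expect_equal(res$m_selected, 1)                     # 0.9 >= 0.85 already
  res2 <- pnp_decompose(H, energy = 0.95)
  expect_equal(res2$m_selected, 2)
  expect_error(pnp_decompose(matrix(0, 3, 2)),
               class = "genpnp_decomposition_error")
  expect_error(pnp_decompose(H, energy = 0), class = "genpnp_parameter_error")
})

test_that("PNP invariants hold on random matrices", {
  for (seed in 1:10) {
    H <- withr::with_seed(seed, matrix(rnorm(15 * 6), 15, 6))
    sv <- svd(H)
    expect_lt(norm(H - sv$u %*% diag(sv$d) %*% t(sv$v), "F"),
              1e-8 * norm(H, "F"))
    res <- pnp_decompose(H, energy = 0.85)
    expect_equal(sum(res$energy_fraction), 1, tolerance = 1e-10)
    expect_true(all(diff(res$energy_fraction) <= 1e-12))
    cum <- cumsum(res$energy_fraction)
    expect_gte(cum[res$m_selected], 0.85 - 1e-12)
    if (res$m_selected > 1) expect_lt(cum[res$m_selected - 1], 0.85)
    expect_true(all(res$distances$distance >= 0))
  }
})

test_that("full energy makes the distance the Euclidean row norm", {
  H <- withr::with_seed(3, matrix(rnorm(12 * 5), 12, 5))
  res <- pnp_decompose(H, energy = 1)
  expect_equal(res$distances$distance, sqrt(rowSums(H^2)), tolerance = 1e-10)
  # rotating the row space leaves all distances unchanged
  Q <- qr.Q(qr(withr::with_seed(4, matrix(rnorm(25), 5, 5))))
  res_rot <- pnp_decompose(H %*% Q, energy = 1)
  expect_equal(res_rot$distances$distance, res$distances$distance,
               tolerance = 1e-10)
})

test_that("rank-one matrices have the closed-form distance |u_k|*||v||", {
  u <- withr::with_seed(5, rnorm(9)); v <- withr::with_seed(6, rnorm(4))
  res <- pnp_decompose(u %*% t(v), energy = 0.85)
  expect_equal(res$m_selected, 1)
  expect_equal(res$distances$distance, abs(u) * sqrt(sum(v^2)),
               tolerance = 1e-10)
})

test_that("core extraction honours thresholds, top counts and ties", {
  genes <- c("G1", "G2"); mirnas <- "M1"
  gen <- toy_gen(tibble::tibble(
    source = c("G1", "G2", "M1"), target = c("G2", "G1", "G1"),
    edge_type = c("tf", "tf", "mirna"), coefficient = c(0.7, 0.4, -0.5),
    stage = "I"))
  pnp <- pnp_decompose(assemble_network_matrix(gen, genes, mirnas), energy = 1)

  # thresholds above the maximum distance leave an empty core
  hi <- max(pnp$distances$distance) + 1
  empty <- extract_core(pnp, mode = "threshold",
                        thresholds = c(protein = hi, gene = hi, mirna = hi))
  expect_equal(nrow(empty$nodes), 0)

  # zero thresholds keep every node (inclusive comparison)
  full <- extract_core(pnp, mode = "threshold",
                       thresholds = c(protein = 0, gene = 0, mirna = 0))
  expect_equal(nrow(full$nodes), 5)
  expect_error(extract_core(pnp, mode = "threshold",
                            thresholds = c(protein = -1, gene = 0, mirna = 0)),
               class = "genpnp_parameter_error")

  # top-count mode picks the largest distances; ties break lexicographically
  top <- extract_core(pnp, mode = "top",
                      top_counts = c(protein = 1, gene = 1, mirna = 1),
                      gen = gen)
  expect_equal(nrow(top$nodes), 3)
  tied <- pnp$distances
  tied$distance <- 1
  pnp_tied <- pnp; pnp_tied$distances <- tied
  t1 <- extract_core(pnp_tied, mode = "top",
                     top_counts = c(protein = 1, gene = 1, mirna = 1))
  expect_equal(sort(t1$nodes$node[t1$nodes$role == "gene"]), "G1")
})

test_that("the induced core subnetwork keeps only edges among core nodes", {
  genes <- c("G1", "G2", "G3"); mirnas <- "M1"
  gen <- toy_gen(tibble::tibble(
    source = c("G1", "G2", "M1"), target = c("G2", "G3", "G1"),
    edge_type = c("tf", "tf", "mirna"), coefficient = c(0.7, 0.6, -0.5),
    stage = "I"))
  pnp <- pnp_decompose(assemble_network_matrix(gen, genes, mirnas), energy = 1)
  core <- extract_core(pnp, mode = "threshold",
                       thresholds = c(protein = 0, gene = 0, mirna = Inf),
                       gen = gen)
  # miRNA not core: its edge is excluded; both TF edges survive
  expect_setequal(core$edges$edge_type, "tf")
})

test_that("component significance controls its level and detects shifts", {
  make_core <- function(nodes) {
    structure(list(
      nodes = tibble::tibble(node = nodes, role = "gene",
                             distance = 1, rank = seq_along(nodes)),
      edges = NULL, mode = "top", params = NULL), class = "core_gen")
  }
  n_genes <- 40; n <- 25
  withr::with_seed(7, {
    null_expr <- matrix(rlnorm(n_genes * 2 * n), n_genes, 2 * n,
                        dimnames = list(paste0("G", 1:n_genes),
                                        paste0("S", 1:(2 * n))))
  })
  mi <- matrix(1, 1, 2 * n, dimnames = list("M1", paste0("S", 1:(2 * n))))
  me <- matrix(0.2, n_genes, 2 * n,
               dimnames = list(paste0("G", 1:n_genes), paste0("S", 1:(2 * n))))
  ds <- tiny_dataset(null_expr, mi, me, rep(c("normal", "I"), each = n))
  res <- component_significance(make_core(paste0("G", 1:n_genes)), ds, "I")
  expect_lt(attr(res, "significant_fraction"), 0.2)   # near the nominal level

  # three-sigma shift on the log scale: essentially every component detected
  shifted <- null_expr
  shifted[, (n + 1):(2 * n)] <- shifted[, (n + 1):(2 * n)] * exp(3)
  ds_shift <- tiny_dataset(shifted, mi, me, rep(c("normal", "I"), each = n))
  res2 <- component_significance(make_core(paste0("G", 1:n_genes)), ds_shift, "I")
  expect_gte(attr(res2, "significant_fraction"), 0.95)

  # empty core and missing normals
  empty <- component_significance(make_core(character(0)), ds, "I")
  expect_equal(nrow(empty), 0)
  ds_no_norm <- tiny_dataset(null_expr, mi, me, rep("I", 2 * n))
  expect_error(component_significance(make_core("G1"), ds_no_norm, "I"),
               class = "genpnp_validation_error")
})
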