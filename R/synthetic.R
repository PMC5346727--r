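#' Configuration for the synthetic GEN generator
#'
#' Describes the size, connectivity, coefficient ranges and noise levels of
#' a simulated genetic and epigenetic network study.  The defaults define
#' the package's reference fixture: 30 genes of which 20 act as proteins
#' (12 of those as transcription factors) and 10 as regulated target genes,
#' 10 miRNAs, 200 samples per stage, and the five stage groups
#' `normal, I, II, III, IV`.
#'
#' Gene roles partition the gene id space. *TF genes* are exogenous drivers:
#' their expression is drawn lognormally and feeds both network layers.
#' *Responsive proteins* obey the bilinear protein-interaction model
#' exactly; each one's partner set consists of a *private* primary TF (used
#' by no other responsive protein, with an interaction ability from the
#' upper half of the magnitude range) plus optional shared hub TFs.  The
#' private driver gives every responsive protein abundance variability that
#' is independent of all other responsive proteins -- the property that
#' makes false candidate partners between responsive proteins statistically
#' prunable rather than able to absorb the target's own noise.  *Regulated
#' genes* obey the methylation-attenuated transcription model exactly, with
#' TF activators/repressors and miRNA repressors.
#'
#' @param n_genes,n_tfs,n_proteins,n_mirnas Node counts; proteins are the
#'   first `n_proteins` genes and TFs the first `n_tfs` proteins, the
#'   remaining `n_genes - n_proteins` genes are the regulated targets.
#' @param samples_per_stage Samples simulated per stage group.
#' @param stages Stage groups, in progression order starting at `normal`.
#' @param tf_per_gene,mirna_per_gene Mean number of true TF / miRNA
#'   regulators per regulated gene (Poisson-distributed per gene; 0 gives
#'   empty edge sets).
#' @param partners_per_protein Mean number of interaction partners per
#'   responsive protein (at least one, drawn from the TF pool, whenever the
#'   density is positive).
#' @param a_range Magnitude range of TF binding abilities; signs are random.
#'   The lower end keeps true effects away from zero so that recovery is a
#'   meaningful benchmark.
#' @param b_range Range of (non-negative) miRNA repression abilities.
#' @param c_range Magnitude range of protein interaction abilities; signs
#'   are random.
#' @param k0_range,k_guard Basal transcription: `k = k0 + k_guard *
#'   sum(|a|) * median(TF level)`, which keeps the transcription balance
#'   positive even under strong repression.
#' @param h_range Basal protein abundance range.
#' @param e_range Translation-rate range (used only by full-protein
#'   simulation).
#' @param full_h_scale Basal-level rescaling applied by the full-protein
#'   simulation, which works on the abundance scale set by the translation
#'   term rather than by the proxy basal level.
#' @param tf_meanlog,tf_sdlog Lognormal parameters of TF expression.
#' @param mirna_meanlog,mirna_sdlog Lognormal parameters of miRNA
#'   expression (median 1 by default).
#' @param meth_base_range Range of baseline per-gene promoter methylation
#'   means.
#' @param meth_shift_frac,meth_shift Fraction of genes whose methylation
#'   mean drifts between consecutive stages, and the per-transition drift on
#'   the beta scale (random fixed direction per gene).
#' @param meth_concentration Concentration of the per-sample Beta draw
#'   around the stage mean (`Inf` makes methylation exactly the mean).
#' @param mirna_shift_frac,mirna_shift_lfc Fraction of miRNAs deregulated
#'   along progression and the per-transition log-fold change.
#' @param tf_shift_frac,tf_shift_lfc Fraction of TFs differentially
#'   expressed along progression and the per-transition log-fold change.
#' @param sigma_v,sigma_w Standard deviations of the additive noise of the
#'   transcription and protein models.
#' @param rho Decoy fraction of the candidate edge sets, in `[0, 1)`.
#' @param denominator_cap Stability bound on the interaction load
#'   \eqn{|\sum_q c_{pq} y_q|} of every protein; samples exceeding it are
#'   redrawn.
#' @param max_retries Redraw rounds allowed before simulation aborts.
#' @param seed Integer seed making the ground truth reproducible.
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(n_genes = 30, n_tfs = 12, n_proteins = 20,
                             n_mirnas = 10, samples_per_stage = 200,
                             stages = c("normal", "I", "II", "III", "IV"),
                             tf_per_gene = 2, mirna_per_gene = 1,
                             partners_per_protein = 2,
                             a_range = c(0.3, 1), b_range = c(0.1, 0.5),
                             c_range = c(0.02, 0.1),
                             k0_range = c(1, 3), k_guard = 1.5,
                             h_range = c(12, 20), e_range = c(0.5, 1.5),
                             full_h_scale = 0.05,
                             tf_meanlog = log(2.5), tf_sdlog = 0.5,
                             mirna_meanlog = 0, mirna_sdlog = 0.4,
                             meth_base_range = c(0.1, 0.3),
                             meth_shift_frac = 0.3, meth_shift = 0.15,
                             meth_concentration = 30,
                             mirna_shift_frac = 0.3, mirna_shift_lfc = 0.5,
                             tf_shift_frac = 0.25, tf_shift_lfc = 0.3,
                             sigma_v = 0.1, sigma_w = 0.05, rho = 0.3,
                             denominator_cap = 0.8, max_retries = 200,
                             seed = 1) {
  cfg <- as.list(environment())
  if (n_genes < 1 || n_mirnas < 0 || samples_per_stage < 1) {
    stop_genpnp("Counts must be positive.", "config_error")
  }
  if (n_tfs > n_proteins || n_proteins > n_genes) {
    stop_genpnp("Need n_tfs <= n_proteins <= n_genes.", "config_error")
  }
  if (rho < 0 || rho >= 1) {
    stop_genpnp("`rho` must lie in [0, 1).", "config_error")
  }
  if (tf_per_gene > n_tfs) {
    stop_genpnp("`tf_per_gene` exceeds the number of TFs.", "config_error")
  }
  if (mirna_per_gene > n_mirnas) {
    stop_genpnp("`mirna_per_gene` exceeds the number of miRNAs.", "config_error")
  }
  if (partners_per_protein > max(n_proteins - 1, 0)) {
    stop_genpnp("`partners_per_protein` exceeds the number of possible partners.",
                "config_error")
  }
  structure(cfg, class = "generator_config")
}

gene_ids_of <- function(cfg) sprintf("G%0*d", max(2, nchar(cfg$n_genes)), seq_len(cfg$n_genes))
mirna_ids_of <- function(cfg) sprintf("MIR%0*d", max(2, nchar(max(cfg$n_mirnas, 1))), seq_len(cfg$n_mirnas))

runif_signed <- function(n, range) {
  sample(c(-1, 1), n, replace = TRUE) * runif(n, range[1], range[2])
}

#' Ground truth of a synthetic GEN study
#'
#' Lower-level constructor for a hand-specified ground truth; most users
#' will call [generate_truth()] instead.  All components use the generator's
#' internal conventions: `tf_edges` carries signed abilities `a`,
#' `mirna_edges` non-negative repression abilities `b`, `ppi_pairs`
#' canonical unordered pairs with signed abilities `c`; `meth_means`,
#' `mirna_scale` and `tf_scale` are feature-by-stage matrices.
#'
#' @param config A [generator_config()].
#' @param roles List with character vectors `tfs`, `responsive`,
#'   `regulated`, `proteins`, `genes`, `mirnas`.
#' @param tf_edges,mirna_edges,ppi_pairs Edge tibbles (see Description).
#' @param k,h,e Tibbles of basal transcription levels (`gene`, `k`), basal
#'   protein levels (`protein`, `h`) and translation rates (`protein`, `e`).
#' @param meth_means,mirna_scale,tf_scale Stage-profile matrices.
#' @return An object of class `synthetic_truth`.
#' @export
synthetic_truth <- function(config, roles, tf_edges, mirna_edges, ppi_pairs,
                            k, h, e, meth_means, mirna_scale, tf_scale) {
  if (any(mirna_edges$b < 0) || any(k$k < 0) || any(h$h < 0)) {
    stop_genpnp("Repression abilities and basal levels must be non-negative.",
                "validation_error")
  }
  if (any(meth_means < 0 | meth_means > 1)) {
    stop_genpnp("Methylation means must lie in [0, 1].", "validation_error")
  }
  structure(
    list(config = config, roles = roles, tf_edges = tf_edges,
         mirna_edges = mirna_edges, ppi_pairs = ppi_pairs,
         k = k, h = h, e = e, meth_means = meth_means,
         mirna_scale = mirna_scale, tf_scale = tf_scale),
    class = "synthetic_truth"
  )
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat(sprintf(
    "<synthetic_truth> %d genes (%d TFs, %d proteins), %d miRNAs; %d tf, %d mirna, %d ppi true edges\n",
    length(x$roles$genes), length(x$roles$tfs), length(x$roles$proteins),
    length(x$roles$mirnas), nrow(x$tf_edges), nrow(x$mirna_edges),
    nrow(x$ppi_pairs)
  ))
  invisible(x)
}

#' Draw a ground-truth network and its generative parameters
#'
#' Instantiates the structural models of both network layers: signed TF
#' binding abilities with magnitudes bounded away from zero, non-negative
#' miRNA repression abilities, signed protein interaction abilities,
#' positive basal levels, per-stage methylation means (drifting for a
#' designated gene subset), and per-stage miRNA / TF expression scalings.
#' Reproducible: the same configuration (including its seed) yields an
#' identical truth.
#'
#' @param config A [generator_config()].
#' @return A [synthetic_truth()].
#' @export
generate_truth <- function(config) {
  cfg <- config
  genes <- gene_ids_of(cfg)
  mirnas <- mirna_ids_of(cfg)
  roles <- list(
    genes = genes,
    mirnas = mirnas,
    proteins = genes[seq_len(cfg$n_proteins)],
    tfs = genes[seq_len(cfg$n_tfs)],
    responsive = genes[setdiff(seq_len(cfg$n_proteins), seq_len(cfg$n_tfs))],
    regulated = if (cfg$n_proteins < cfg$n_genes)
      genes[(cfg$n_proteins + 1):cfg$n_genes] else character(0)
  )
  n_stage <- length(cfg$stages)

  withr::with_seed(cfg$seed, {
    draw_count <- function(mean, cap) {
      if (mean <= 0) 0L else min(rpois(1, mean), cap)
    }

    tf_edges <- purrr::map(roles$regulated, function(g) {
      nk <- draw_count(cfg$tf_per_gene, cfg$n_tfs)
      if (nk == 0) return(NULL)
      tibble(source = sample(roles$tfs, nk), target = g,
             a = runif_signed(nk, cfg$a_range))
    })
    tf_edges <- dplyr::bind_rows(tf_edges)
    if (nrow(tf_edges) == 0) tf_edges <- tibble(source = character(0), target = character(0), a = numeric(0))

    mirna_edges <- purrr::map(roles$regulated, function(g) {
      nk <- draw_count(cfg$mirna_per_gene, cfg$n_mirnas)
      if (nk == 0) return(NULL)
      tibble(source = sample(mirnas, nk), target = g,
             b = runif(nk, cfg$b_range[1], cfg$b_range[2]))
    })
    mirna_edges <- dplyr::bind_rows(mirna_edges)
    if (nrow(mirna_edges) == 0) mirna_edges <- tibble(source = character(0), target = character(0), b = numeric(0))

    # every responsive protein gets a private primary TF partner used by no
    # other responsive protein, plus extra partners from a disjoint pool of
    # shared hub TFs.  The private driver gives each responsive protein
    # abundance variability independent of every other responsive protein,
    # which is what makes decoy partners between responsive proteins
    # prunable; TF-only partner sets also rule out amplification loops
    # among responsive proteins.
    n_resp <- length(roles$responsive)
    primaries <- if (cfg$n_tfs > 0 && n_resp > 0) {
      rep(sample(roles$tfs), length.out = n_resp)
    } else character(0)
    hub_pool <- setdiff(roles$tfs, primaries[seq_len(min(n_resp, cfg$n_tfs))])
    ppi <- purrr::map(seq_len(n_resp), function(i) {
      p <- roles$responsive[i]
      if (cfg$partners_per_protein <= 0 || cfg$n_tfs == 0) return(NULL)
      extra <- min(rpois(1, max(cfg$partners_per_protein - 1, 0)),
                   length(hub_pool))
      partners <- c(primaries[i], if (extra > 0) sample(hub_pool, extra))
      tibble(source = p, target = partners,
             primary = partners == primaries[i])
    })
    ppi <- dplyr::bind_rows(ppi)
    if (is.null(ppi) || nrow(ppi) == 0) {
      ppi_pairs <- tibble(source = character(0), target = character(0), c = numeric(0))
    } else {
      ppi_pairs <- dplyr::distinct(
        dplyr::mutate(canonical_pairs(ppi), primary = ppi$primary))
      # primary interactions draw from the upper part of the magnitude
      # range: the private driver is the protein's dominant interaction
      prim_lo <- cfg$c_range[1] + 0.5 * diff(range(cfg$c_range))
      ppi_pairs$c <- ifelse(
        ppi_pairs$primary,
        runif_signed(nrow(ppi_pairs), c(prim_lo, cfg$c_range[2])),
        runif_signed(nrow(ppi_pairs), cfg$c_range)
      )
      ppi_pairs <- ppi_pairs[, c("source", "target", "c")]
    }

    abs_a_sum <- vapply(roles$regulated, function(g)
      sum(abs(tf_edges$a[tf_edges$target == g])), numeric(1),
      USE.NAMES = FALSE)
    k <- tibble(
      gene = roles$regulated,
      k = runif(length(roles$regulated), cfg$k0_range[1], cfg$k0_range[2]) +
        cfg$k_guard * abs_a_sum * exp(cfg$tf_meanlog)
    )
    h <- tibble(protein = roles$proteins,
                h = runif(cfg$n_proteins, cfg$h_range[1], cfg$h_range[2]))
    e <- tibble(protein = roles$proteins,
                e = runif(cfg$n_proteins, cfg$e_range[1], cfg$e_range[2]))

    stage_idx <- seq_len(n_stage) - 1
    base <- runif(cfg$n_genes, cfg$meth_base_range[1], cfg$meth_base_range[2])
    shifted <- seq_len(cfg$n_genes) %in%
      sample(cfg$n_genes, floor(cfg$meth_shift_frac * cfg$n_genes))
    dir <- sample(c(-1, 1), cfg$n_genes, replace = TRUE)
    meth_means <- matrix(
      sapply(stage_idx, function(s)
        pmin(pmax(base + ifelse(shifted, dir * cfg$meth_shift * s, 0), 0.02), 0.98)),
      nrow = cfg$n_genes, dimnames = list(genes, cfg$stages))

    stage_scale <- function(n, frac, lfc, ids) {
      de <- seq_len(n) %in% sample(n, floor(frac * n))
      dir <- sample(c(-1, 1), n, replace = TRUE)
      m <- vapply(stage_idx, function(s)
        exp(ifelse(de, dir * lfc * s, 0)), numeric(n))
      matrix(m, nrow = n, ncol = length(stage_idx),
             dimnames = list(ids, cfg$stages))
    }
    mirna_scale <- stage_scale(cfg$n_mirnas, cfg$mirna_shift_frac,
                               cfg$mirna_shift_lfc, mirnas)
    tf_scale <- stage_scale(cfg$n_tfs, cfg$tf_shift_frac,
                            cfg$tf_shift_lfc, roles$tfs)

    synthetic_truth(cfg, roles, tf_edges, mirna_edges, ppi_pairs,
                    k, h, e, meth_means, mirna_scale, tf_scale)
  })
}

#' True edges in the identified-network sign convention
#'
#' Expresses the ground-truth network as an edge table comparable with
#' [identify_gen()] output: TF abilities `a`, miRNA repressions `-b`,
#' protein interactions `c` (one row per modelled direction).
#'
#' @param truth A [synthetic_truth()].
#' @param stage Stage label to stamp on the rows.
#' @return An [identified_gen()]-style edge tibble.
#' @export
truth_edges <- function(truth, stage = NA_character_) {
  dplyr::bind_rows(
    tibble(source = truth$tf_edges$source, target = truth$tf_edges$target,
           edge_type = "tf", coefficient = truth$tf_edges$a),
    tibble(source = truth$mirna_edges$source, target = truth$mirna_edges$target,
           edge_type = "mirna", coefficient = -truth$mirna_edges$b),
    {
      terms <- ppi_terms(truth)
      tibble(source = terms$partner, target = terms$protein,
             edge_type = "ppi", coefficient = terms$c)
    }
  ) |>
    dplyr::mutate(stage = stage)
}

# directed interaction terms: one row per (modelled protein, partner)
ppi_terms <- function(truth) {
  pp <- truth$ppi_pairs
  resp <- truth$roles$responsive
  dplyr::bind_rows(
    tibble(protein = pp$source, partner = pp$target, c = pp$c),
    tibble(protein = pp$target, partner = pp$source, c = pp$c)
  ) |>
    dplyr::filter(.data$protein %in% resp)
}

# ---- simulation ------------------------------------------------------------

#' Simulate one stage of omics profiles from a ground truth
#'
#' Draws TF and miRNA expression and per-gene methylation, then computes
#' every modelled node's expression by solving its structural equation in
#' closed form, so that at zero noise the generating equations hold with
#' zero residual at the true parameters:
#' * regulated genes: \eqn{x_i = (\sum_j a_{ij} y_j h(\beta_i) + k_i
#'   h(\beta_i) + v_i) / (1 + \sum_m b_{im} s_m)} -- the repression
#'   denominator is at least 1, so the solve is always defined;
#' * responsive proteins (mRNA-proxy form): the coupled bilinear system
#'   \eqn{y_p = (h_p + w_p) / (1 - \sum_q c_{pq} y_q)} is solved by
#'   fixed-point iteration; samples whose interaction load
#'   \eqn{|\sum_q c_{pq} y_q|} exceeds `denominator_cap` are redrawn.
#'
#' With `protein_mode = "full"`, protein abundance is simulated from the
#' full interaction model including the translation term \eqn{e_p x_p}
#' (mRNA drawn exogenously) and returned in the dataset's `protein_expr`
#' element.
#'
#' @param truth A [synthetic_truth()].
#' @param stage Stage label (must be a column of the truth's stage
#'   profiles).
#' @param L Number of samples (default: the configured samples per stage).
#' @param seed Integer seed.
#' @param protein_mode `"proxy"` (default) or `"full"`.
#' @return An [omics_dataset()] whose samples all carry `stage`; in full
#'   mode it additionally contains a `protein_expr` matrix.
#' @export
simulate_stage <- function(truth, stage, L = truth$config$samples_per_stage,
                           seed = truth$config$seed, protein_mode = c("proxy", "full")) {
  protein_mode <- match.arg(protein_mode)
  cfg <- truth$config
  if (!stage %in% colnames(truth$meth_means)) {
    stop_genpnp(sprintf("Stage '%s' has no methylation profile in this truth.", stage),
                "validation_error")
  }
  roles <- truth$roles
  n_tf <- length(roles$tfs); n_resp <- length(roles$responsive)
  n_reg <- length(roles$regulated); n_prot <- length(roles$proteins)

  # coefficient matrices
  A <- matrix(0, n_reg, n_tf, dimnames = list(roles$regulated, roles$tfs))
  if (nrow(truth$tf_edges)) {
    A[cbind(truth$tf_edges$target, truth$tf_edges$source)] <- truth$tf_edges$a
  }
  B <- matrix(0, n_reg, cfg$n_mirnas, dimnames = list(roles$regulated, roles$mirnas))
  if (nrow(truth$mirna_edges)) {
    B[cbind(truth$mirna_edges$target, truth$mirna_edges$source)] <- truth$mirna_edges$b
  }
  Cmat <- matrix(0, n_prot, n_prot, dimnames = list(roles$proteins, roles$proteins))
  if (nrow(truth$ppi_pairs)) {
    Cmat[cbind(truth$ppi_pairs$source, truth$ppi_pairs$target)] <- truth$ppi_pairs$c
    Cmat[cbind(truth$ppi_pairs$target, truth$ppi_pairs$source)] <- truth$ppi_pairs$c
  }
  Cr <- Cmat[roles$responsive, , drop = FALSE]
  kv <- setNames(truth$k$k, truth$k$gene)[roles$regulated]
  hv <- setNames(truth$h$h, truth$h$protein)
  ev <- setNames(truth$e$e, truth$e$protein)
  mu <- truth$meth_means[, stage]
  kap <- cfg$meth_concentration

  withr::with_seed(seed, {
    draw_block <- function(n) {
      # one candidate draw of every exogenous quantity for n samples
      Ytf <- matrix(
        rlnorm(n_tf * n, meanlog = cfg$tf_meanlog + log(truth$tf_scale[, stage]),
               sdlog = cfg$tf_sdlog),
        n_tf, n, dimnames = list(roles$tfs, NULL))
      S <- matrix(
        rlnorm(cfg$n_mirnas * n, meanlog = cfg$mirna_meanlog +
                 log(truth$mirna_scale[, stage]), sdlog = cfg$mirna_sdlog),
        cfg$n_mirnas, n, dimnames = list(roles$mirnas, NULL))
      Beta <- if (is.infinite(kap)) {
        matrix(mu, cfg$n_genes, n, dimnames = list(roles$genes, NULL))
      } else {
        matrix(rbeta(cfg$n_genes * n, mu * kap, (1 - mu) * kap),
               cfg$n_genes, n, dimnames = list(roles$genes, NULL))
      }
      W <- matrix(rnorm(n_resp * n, 0, cfg$sigma_w), n_resp, n,
                  dimnames = list(roles$responsive, NULL))
      V <- matrix(rnorm(n_reg * n, 0, cfg$sigma_v), n_reg, n,
                  dimnames = list(roles$regulated, NULL))
      Xm <- matrix(  # protein mRNA, used in full mode only
        rlnorm(n_prot * n, meanlog = cfg$tf_meanlog, sdlog = cfg$tf_sdlog),
        n_prot, n, dimnames = list(roles$proteins, NULL))
      list(Ytf = Ytf, S = S, Beta = Beta, W = W, V = V, Xm = Xm)
    }

    solve_block <- function(blk) {
      n <- ncol(blk$Ytf)
      Yprot <- matrix(0, n_prot, n, dimnames = list(roles$proteins, NULL))
      Yprot[roles$tfs, ] <- blk$Ytf
      ok <- rep(TRUE, n)
      if (n_resp > 0) {
        drive <- hv[roles$responsive] + blk$W
        Yresp <- drive
        delta <- matrix(Inf, n_resp, n)
        for (it in seq_len(200)) {
          Yprot[roles$responsive, ] <- Yresp
          load <- Cr %*% Yprot
          denom <- 1 - load
          # freeze near-singular denominators; those columns are rejected below
          denom[denom < 0.1] <- 0.1
          Ynew <- drive / denom
          delta <- abs(Ynew - Yresp)
          Yresp <- Ynew
          if (max(delta) < 1e-13) break
        }
        Yprot[roles$responsive, ] <- Yresp
        load <- Cr %*% Yprot
        ok <- ok &
          apply(abs(load) <= cfg$denominator_cap, 2, all) &
          apply(Yresp > 0 & is.finite(Yresp), 2, all) &
          (apply(delta, 2, max) < 1e-10)
      }
      X <- matrix(0, cfg$n_genes, n, dimnames = list(roles$genes, NULL))
      X[roles$proteins, ] <- Yprot
      if (n_reg > 0) {
        Hb <- methylation_attenuation(blk$Beta[roles$regulated, , drop = FALSE])
        numer <- (A %*% blk$Ytf) * Hb + kv * Hb + blk$V
        ok <- ok & apply(numer > 0, 2, all)
        X[roles$regulated, ] <- numer / (1 + B %*% blk$S)
      }
      list(X = X, ok = ok)
    }

    blk <- draw_block(L)
    sol <- solve_block(blk)
    retries <- 0
    while (any(!sol$ok)) {
      retries <- retries + 1
      if (retries > cfg$max_retries) {
        stop_genpnp(
          "Simulation kept producing unstable samples; use a smaller |c| range or weaker interactions.",
          "generation_error"
        )
      }
      bad <- which(!sol$ok)
      redo <- draw_block(length(bad))
      for (nm in names(blk)) blk[[nm]][, bad] <- redo[[nm]]
      sol <- solve_block(blk)
    }

    samples <- sprintf("%s_S%03d", stage, seq_len(L))
    gene_expr <- sol$X
    methylation <- blk$Beta
    colnames(gene_expr) <- colnames(methylation) <- samples
    mirna_expr <- blk$S
    colnames(mirna_expr) <- samples

    ds <- omics_dataset(gene_expr, mirna_expr, methylation,
                        tibble(sample = samples, stage = stage))

    if (protein_mode == "full") {
      # full model: y_p = (sum_q c_pq y_q y_p) + e_p x_p + h_p + w_p with
      # exogenous mRNA x_p.  Only responsive proteins carry interaction
      # terms; TF-protein abundance is translation plus basal.  Basal
      # levels are rescaled so that the interaction loads of the
      # abundance-bearing model stay in the stable regime.
      n <- L
      Wp <- matrix(0, n_prot, n, dimnames = list(roles$proteins, NULL))
      if (n_resp > 0) Wp[roles$responsive, ] <- blk$W
      hf <- hv * cfg$full_h_scale
      drive <- ev * blk$Xm + hf + Wp
      Yfull <- drive
      if (n_resp > 0) {
        for (it in seq_len(100)) {
          load <- Cmat[roles$responsive, , drop = FALSE] %*% Yfull
          Ynew <- drive
          Ynew[roles$responsive, ] <- drive[roles$responsive, ] / (1 - load)
          if (max(abs(Ynew - Yfull)) < 1e-13) { Yfull <- Ynew; break }
          Yfull <- Ynew
        }
      }
      gene_expr[roles$proteins, ] <- blk$Xm
      ds <- omics_dataset(gene_expr, mirna_expr, methylation, ds$stages)
      colnames(Yfull) <- samples
      ds$protein_expr <- Yfull
    }
    ds
  })
}

#' Simulate a complete multi-stage dataset
#'
#' Calls [simulate_stage()] for each requested stage with seeds derived
#' from `seed` and binds the results into one dataset.
#'
#' @inheritParams simulate_stage
#' @param stages Stage labels to simulate.
#' @return An [omics_dataset()].
#' @export
simulate_dataset <- function(truth, stages = truth$config$stages,
                             L = truth$config$samples_per_stage,
                             seed = truth$config$seed) {
  parts <- purrr::map2(stages, seq_along(stages), function(s, i)
    simulate_stage(truth, s, L = L, seed = seed + 1000L * i))
  omics_dataset(
    do.call(cbind, lapply(parts, `[[`, "gene_expr")),
    do.call(cbind, lapply(parts, `[[`, "mirna_expr")),
    do.call(cbind, lapply(parts, `[[`, "methylation")),
    dplyr::bind_rows(lapply(parts, `[[`, "stages"))
  )
}

# ---- candidate corruption and recovery scoring -----------------------------

#' Contaminate the true network with decoy candidate edges
#'
#' Emulates the false positives introduced by database mining: the
#' candidate network presented to identification is the union of the true
#' edges and decoys sampled uniformly from the non-edges of each layer's
#' role structure (TF x regulated gene, miRNA x regulated gene, and
#' responsive-protein pairs).  The decoy count per layer is chosen so that
#' decoys make up a fraction `rho` of the candidate set.  Decoys never
#' duplicate true edges.  The decoy lists are attached to the result as the
#' `"decoys"` attribute for recovery scoring.
#'
#' @param truth A [synthetic_truth()].
#' @param rho Decoy fraction in `[0, 1)` (default: the configured value).
#' @param seed Integer seed.
#' @return A [candidate_gen()] with a `"decoys"` attribute.
#' @export
corrupt_candidates <- function(truth, rho = truth$config$rho,
                               seed = truth$config$seed) {
  if (rho < 0 || rho >= 1) stop_genpnp("`rho` must lie in [0, 1).", "config_error")
  roles <- truth$roles
  withr::with_seed(seed, {
    sample_nonedges <- function(all_pairs, true_pairs, n_true) {
      pool <- dplyr::anti_join(all_pairs, true_pairs, by = c("source", "target"))
      n_decoy <- min(round(rho / (1 - rho) * n_true), nrow(pool))
      pool[sample(nrow(pool), n_decoy), , drop = FALSE]
    }
    cross <- function(src, tgt) {
      if (length(src) == 0 || length(tgt) == 0)
        return(tibble(source = character(0), target = character(0)))
      tidyr::expand_grid(source = src, target = tgt)
    }
    tf_true <- truth$tf_edges[, c("source", "target")]
    tf_decoys <- sample_nonedges(cross(roles$tfs, roles$regulated),
                                 tf_true, nrow(tf_true))
    mi_true <- truth$mirna_edges[, c("source", "target")]
    mi_decoys <- sample_nonedges(cross(roles$mirnas, roles$regulated),
                                 mi_true, nrow(mi_true))
    resp_pairs <- if (length(roles$responsive) >= 2) {
      canonical_pairs(as_tibble(t(utils::combn(roles$responsive, 2)),
                                .name_repair = ~c("source", "target")))
    } else tibble(source = character(0), target = character(0))
    pp_true <- truth$ppi_pairs[, c("source", "target")]
    pp_decoys <- sample_nonedges(resp_pairs, pp_true, nrow(pp_true))

    out <- suppressWarnings(candidate_gen(
      tf_edges = dplyr::bind_rows(tf_true, tf_decoys),
      mirna_edges = dplyr::bind_rows(mi_true, mi_decoys),
      ppi_edges = dplyr::bind_rows(pp_true, pp_decoys)
    ))
    attr(out, "decoys") <- list(tf = tf_decoys, mirna = mi_decoys, ppi = pp_decoys)
    out
  })
}

#' Score an identified network against the generating truth
#'
#' Compares the surviving edges of an [identified_gen()] with the ground
#' truth that generated the data.  Directed layers (TF, miRNA) are compared
#' as directed edge sets; the protein layer is compared as unordered pairs,
#' an interaction counting as recovered when either endpoint's regression
#' retained it.  Reported measures:
#'
#' * `precision`, `recall`: pooled over the three layers (with `grn_*` and
#'   `ppi_*` per-layer columns).  An empty identified set has undefined
#'   precision, reported as 1 with `precision_defined = FALSE`.
#' * `sign_accuracy`: fraction of recovered modelled coefficients whose
#'   sign matches the truth.
#' * `coef_rmse`: root-mean-square error over all true modelled
#'   coefficients, a missed edge entering with coefficient 0.
#' * `node_exact_fraction`: fraction of scored nodes whose recovered
#'   regulator/partner set equals the true set exactly.  When `candidates`
#'   are supplied, the scored nodes are those with at least one candidate
#'   (the nodes where pruning had a decision to make).
#'
#' @param truth A [synthetic_truth()].
#' @param identified An [identified_gen()] fitted on data simulated from
#'   `truth`.
#' @param candidates Optionally, the [corrupt_candidates()] output used for
#'   the fit.
#' @return A one-row tibble.
#' @export
score_recovery <- function(truth, identified, candidates = NULL) {
  truth_ids <- c(truth$roles$genes, truth$roles$mirnas)
  seen_ids <- unique(c(identified$nodes$node, identified$edges$source,
                       identified$edges$target))
  if (length(intersect(truth_ids, seen_ids)) == 0) {
    stop_genpnp("Truth and identified network share no nodes.", "validation_error")
  }
  ed <- identified$edges

  id_tf <- ed[ed$edge_type == "tf", ]
  id_mi <- ed[ed$edge_type == "mirna", ]
  id_pp <- ed[ed$edge_type == "ppi", ]
  id_pp_pairs <- dplyr::distinct(canonical_pairs(id_pp))

  tf_true <- truth$tf_edges[, c("source", "target")]
  mi_true <- truth$mirna_edges[, c("source", "target")]
  pp_true <- truth$ppi_pairs[, c("source", "target")]

  count_hits <- function(id_set, true_set) {
    nrow(dplyr::semi_join(id_set, true_set, by = c("source", "target")))
  }
  tp_tf <- count_hits(dplyr::distinct(id_tf[, c("source", "target")]), tf_true)
  tp_mi <- count_hits(dplyr::distinct(id_mi[, c("source", "target")]), mi_true)
  tp_pp <- count_hits(id_pp_pairs, pp_true)

  n_id_grn <- nrow(dplyr::distinct(id_tf[, c("source", "target")])) +
    nrow(dplyr::distinct(id_mi[, c("source", "target")]))
  n_id_pp <- nrow(id_pp_pairs)
  n_true_grn <- nrow(tf_true) + nrow(mi_true)
  n_true_pp <- nrow(pp_true)

  safe_ratio <- function(num, den) if (den == 0) 1 else num / den
  grn_precision <- safe_ratio(tp_tf + tp_mi, n_id_grn)
  ppi_precision <- safe_ratio(tp_pp, n_id_pp)
  grn_recall <- safe_ratio(tp_tf + tp_mi, n_true_grn)
  ppi_recall <- safe_ratio(tp_pp, n_true_pp)

  # modelled (directed) coefficients: sign accuracy and RMSE
  truth_dir <- truth_edges(truth)[, c("source", "target", "edge_type", "coefficient")]
  names(truth_dir)[4] <- "true_coef"
  matched <- dplyr::left_join(
    truth_dir,
    dplyr::distinct(ed[, c("source", "target", "edge_type", "coefficient")]),
    by = c("source", "target", "edge_type")
  )
  matched$coefficient[is.na(matched$coefficient)] <- 0
  recovered <- matched$coefficient != 0
  sign_accuracy <- if (any(recovered)) {
    mean(sign(matched$coefficient[recovered]) == sign(matched$true_coef[recovered]))
  } else NA_real_
  coef_rmse <- sqrt(mean((matched$coefficient - matched$true_coef)^2))

  # per-node exactness
  gene_nodes <- if (!is.null(candidates)) {
    unique(c(candidates$tf_edges$target, candidates$mirna_edges$target))
  } else unique(c(tf_true$target, mi_true$target))
  prot_nodes <- if (!is.null(candidates)) {
    unique(c(candidates$ppi_edges$source, candidates$ppi_edges$target))
  } else unique(c(pp_true$source, pp_true$target))

  reg_set <- function(edges, node) {
    sort(paste(edges$edge_type[edges$target == node],
               edges$source[edges$target == node]))
  }
  truth_grn_edges <- dplyr::bind_rows(
    tibble(source = tf_true$source, target = tf_true$target, edge_type = "tf"),
    tibble(source = mi_true$source, target = mi_true$target, edge_type = "mirna")
  )
  id_grn_edges <- dplyr::distinct(
    ed[ed$edge_type != "ppi", c("source", "target", "edge_type")])
  gene_exact <- vapply(gene_nodes, function(g)
    identical(reg_set(id_grn_edges, g), reg_set(truth_grn_edges, g)), logical(1))

  incident <- function(pairs, node) {
    sort(c(pairs$target[pairs$source == node], pairs$source[pairs$target == node]))
  }
  prot_exact <- vapply(prot_nodes, function(p)
    identical(incident(id_pp_pairs, p), incident(pp_true, p)), logical(1))

  node_exact <- c(gene_exact, prot_exact)

  tibble(
    precision = safe_ratio(tp_tf + tp_mi + tp_pp, n_id_grn + n_id_pp),
    recall = safe_ratio(tp_tf + tp_mi + tp_pp, n_true_grn + n_true_pp),
    grn_precision = grn_precision, grn_recall = grn_recall,
    ppi_precision = ppi_precision, ppi_recall = ppi_recall,
    sign_accuracy = sign_accuracy,
    coef_rmse = coef_rmse,
    node_exact_fraction = if (length(node_exact)) mean(node_exact) else NA_real_,
    n_true = n_true_grn + n_true_pp,
    n_identified = n_id_grn + n_id_pp,
    precision_defined = (n_id_grn + n_id_pp) > 0
  )
}

#' Write a ground truth as plain-text tables
#'
#' Emits `truth_edges.tsv` (signed-convention edge list),
#' `truth_nodes.tsv` (basal levels and translation rates) and the
#' stage-profile tables under `dir`.
#'
#' @param truth A [synthetic_truth()].
#' @param dir Output directory.
#' @return The written paths, invisibly.
#' @export
write_truth <- function(truth, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, c("truth_edges.tsv", "truth_nodes.tsv",
                            "truth_meth_means.tsv", "truth_mirna_scale.tsv"))
  readr::write_tsv(truth_edges(truth), paths[1], progress = FALSE)
  nodes <- dplyr::bind_rows(
    tibble(node = truth$k$gene, role = "gene", basal = truth$k$k,
           translation = NA_real_),
    tibble(node = truth$h$protein, role = "protein", basal = truth$h$h,
           translation = truth$e$e[match(truth$h$protein, truth$e$protein)])
  )
  readr::write_tsv(nodes, paths[2], progress = FALSE)
  write_matrix_tsv(truth$meth_means, paths[3])
  write_matrix_tsv(truth$mirna_scale, paths[4])
  invisible(paths)
}
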