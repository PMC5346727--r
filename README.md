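# genpnp

Genetic-and-epigenetic network (GEN) identification and principal network
projection in R.

## The problem

Tumour progression is driven jointly by transcriptional regulation and by
epigenetic control: promoter methylation silences genes, and miRNAs repress
their targets post-transcriptionally. Given matched mRNA expression, miRNA
expression and promoter methylation profiles for patient samples grouped
into tumour stages, plus candidate regulatory associations mined from
interaction databases (TF→gene, miRNA→gene, protein–protein), `genpnp`

1. **identifies** a stage-specific network by fitting, per gene and per
   protein, a structural regression model with sign constraints,
2. **prunes** the database false positives by backward elimination under the
   Akaike information criterion (AIC), and
3. **extracts** the *core* network — the nodes carrying the principal
   structure of the identified network — by principal network projection
   (PNP), an SVD-based projection of each node's coefficient profile.

Downstream utilities compare stages (differential methylation/miRNA calls,
edge-polarity consistency, projection-distance correlation), filter
pathway-enrichment tables, and select drugs specific to network markers
from a local drug–gene interaction table. A synthetic-data generator draws
data *exactly* from the structural models, so the whole pipeline is
testable against a known ground truth. It is aimed at systems-biology
researchers who want a reproducible, tested implementation of this class
of network-identification methods.

## The models

Expression of target gene *i* in sample *n* combines TF regulation
attenuated by promoter methylation, miRNA repression proportional to the
target's own abundance, a basal level, and noise:

```
x_{i,n} = Σ_j a_{ij} · y_{j,n} · h(β_{i,n})  −  Σ_m b_{im} · s_{m,n} · x_{i,n}
          + k_i · h(β_{i,n}) + v_{i,n},        h(β) = 1 / (1 + (β/0.5)²)
```

with `b_{im} ≥ 0` and `k_i ≥ 0`. Protein abundance follows a bilinear
interaction model (interaction proportional to the product of both
abundances), fitted by default in *mRNA-proxy* mode where the translation
rate is structurally unidentifiable and omitted:

```
y_{p,n} = Σ_q c_{pq} · y_{q,n} · y_{p,n} + e_p x_{p,n} + h_p + w_{p,n},   h_p ≥ 0
```

Both are rewritten as linear regressions over the stage's samples and
solved by sign-constrained least squares; AIC backward elimination detects
each node's model order. The surviving coefficients are stacked into the
combined network matrix `H` ((2N+M) × N; protein, gene-as-TF and miRNA
blocks), decomposed as `H = U D Vᵀ`, and each row is projected onto the
minimal set of leading singular vectors holding ≥ 85 % of the
eigenexpression `E_m = d_m² / Σ d_n²`. The projection distance
`D(k) = (Σ_m P(k,m)²)^{1/2}` ranks nodes; the top-ranked (or
above-threshold) nodes per role form the core GEN.

## Worked example

```r
library(genpnp)

cfg        <- generator_config(seed = 42)      # 30 genes, 10 miRNAs, 20 proteins
truth      <- generate_truth(cfg)
dataset    <- simulate_dataset(truth)          # 5 stages x 200 samples
candidates <- corrupt_candidates(truth, seed = 43)   # 30% decoy edges

gen <- identify_gen(dataset, candidates, "I")  # constrained LS + AIC pruning
score_recovery(truth, gen, candidates)
#>   precision recall grn_precision grn_recall ppi_precision ppi_recall
#> 1     0.944      1         0.973          1         0.882          1
#>   sign_accuracy coef_rmse node_exact_fraction
#> 1             1    0.0228               0.833
```

Identification recovered every true edge (recall 1), kept precision high
against the 30 % decoy contamination, got every recovered coefficient's
sign right and estimated the coefficients to RMSE ≈ 0.02 on magnitudes of
0.02–1.

```r
nm  <- assemble_network_matrix(gen, truth$roles$genes, truth$roles$mirnas)
pnp <- pnp_decompose(nm)                       # SVD + 85% energy rule
pnp
#> <pnp_result> 4 components selected of 30 (cumulative energy 0.864 >= 0.85)

core <- extract_core(pnp, top_counts = c(protein = 12, gene = 10, mirna = 5),
                     gen = gen)
head(dplyr::arrange(tidy(pnp), dplyr::desc(distance)), 3)
#>       k node  role  distance
#> 1    35 G05   gene     1.73
#> 2    39 G09   gene     1.30
#> 3    34 G04   gene     1.27
```

Four principal components carry 86 % of the network energy; the largest
projection distances belong to the TF genes with the strongest outgoing
regulation. Comparing stages:

```r
gen2 <- identify_gen(dataset, candidates, "II")
polarity_consistency(gen, gen2)
#>   consistency n_shared n_sign_agree n_sign_changed defined
#> 1           1       51           51              0    TRUE

projection_distance_r2(pnp, pnp_decompose(
  assemble_network_matrix(gen2, truth$roles$genes, truth$roles$mirnas)))
#>   r2  n defined
#> 1  1 70    TRUE     # 0.9996 before rounding

dplyr::filter(differential_methylation(dataset, "I", "II"), called)
#>   gene         p mean_a mean_b delta called direction tested
#> 1 G06   8.73e-40  0.282  0.419 0.137 TRUE   hyper     TRUE
#> 2 G22   7.05e-39  0.345  0.501 0.156 TRUE   hyper     TRUE
#> ...
```

The two stage networks share 51 surviving edges, all with consistent
polarity, their projection-distance profiles correlate almost perfectly
(the generating network is the same; only methylation, miRNA and TF levels
shift between stages), and the genes whose methylation means drift by the
configured 0.15 per transition are called hyper-methylated in stage II.

`run_pipeline()` chains all of the above (identification → PNP → core →
stage comparisons → optional drug selection) for every stage from one
configuration list or YAML file, writes each artifact as TSV and records a
manifest of content hashes so reruns can be verified bitwise;
`inst/scripts/genpnp-pipeline.R` is a command-line wrapper around it.

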