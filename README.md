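# allorep

Analysis of directly and indirectly alloreactive T-cell receptor β-chain
repertoires from bulk TCR-seq clonotype tables.

## The problem

After transplantation, recipient T cells are activated through two main
routes: the **direct pathway** (recipient TCRs recognizing intact allogeneic
MHC–peptide complexes on donor cells) and the **indirect pathway**
(donor-derived peptides presented on recipient MHC). Experiments that model
the two pathways separately — mixed lymphocyte cultures with allogeneic or
lysate-loaded dendritic cells, vaccination, skin grafting — produce
multi-sample TCR-β clonotype tables in which the alloreactive clonotypes are
a small, expanded minority. `allorep` implements the complete analysis
chain that isolates and characterizes them:

1. **IO** — MiXCR clone tables and AIRR Rearrangement TSVs in, AIRR and
   GraphML out (`read_mixcr()`, `read_airr()`, `write_airr()`,
   `export_graphml()`).
2. **Normalization** — TMM (trimmed mean of M-values) scale factors on the
   clonotype × sample count matrix: for sample *j* against reference *r*,
   the weighted mean of log-ratios `M = log2((y_ij/N_j)/(y_ir/N_r))` after
   trimming 30% of extreme M and 5% of extreme A values, with
   inverse-variance weights (`tmm_factors()`).
3. **Expansion calling** — an empirical-Bayes negative-binomial two-model
   posterior: for clonotype *i*, H0 assumes one relative abundance *q_i*
   across all samples, H1 group-specific abundances; marginal likelihoods
   average NB likelihoods over an empirical prior of (abundance, dispersion)
   points estimated from sampled clonotypes, and the proportion of
   differentially abundant clonotypes is re-estimated iteratively. Clones
   with posterior likelihood > 0.95 are assigned fold bins 2×–32×
   (`call_expansions()`).
4. **Overlap** — Morisita–Horn index
   `C = 2Σxᵢyᵢ / ((Σxᵢ²/X² + Σyᵢ²/Y²)·X·Y)` between every sample pair, at
   every expansion threshold (`overlap_grid()`).
5. **Similarity graphs** — CDR3s at Hamming distance 1 connected via
   masked-position hashing, cluster statistics including the
   edges/vertices interconnectedness ratio (`build_cdr3_graph()`,
   `cluster_stats()`).
6. **Specificity patterns** — GLIPH2-style local k-mer motifs and
   single-wildcard global templates, Fisher-exact enriched against a
   reference repertoire; patterns shared between the direct and indirect
   arms (unknown pathway origin) are excluded from both
   (`discover_patterns()`, `pattern_set_algebra()`,
   `assign_clonotypes()`).
7. **Features** — labeled-clonotype frequency statistics with Mann–Whitney
   tests, V-gene usage and cosine similarity, CDR3 spectratype with the
   >14 aa ratio, positional amino-acid probability profiles.
8. **Annotation** — exact CDR3 matching against VDJdb / McPAS-TCR style
   specificity databases with pathology breakdowns
   (`annotate_clonotypes()`).

A synthetic-repertoire generator (`simulation_spec()`,
`simulate_scenario()`) produces multi-sample mouse-like CD4⁺ TRB
repertoires with Zipf clone sizes, planted motif-sharing specificity
groups, HD-1 neighbors, V-usage skew and condition-specific expansions,
plus the ground truth needed to validate every stage.

## Worked example

```r
library(allorep)

# simulate a small mixed-culture experiment: direct (BlL0) and indirect
# (BaLBl) stimulations plus two control conditions, 2 mice each
spec <- simulation_spec(n_background = 1000, depth = 5e4, replicates = 2,
                        n_groups_direct = 5, n_groups_indirect = 5,
                        n_groups_shared = 2, seed = 42)
scenario <- simulate_scenario(spec)
run <- run_pipeline(scenario$repertoires,
                    run_config(seed = 1, unstim_top = 1000))
run
#> <allorep_run>
#>   expansion: 49 direct / 48 indirect clonotypes at >= 2x
#>   patterns: 46 direct, 48 indirect, 0 unstim; 13 shared; exclusive 33 / 35
#>   classification: 35 direct, 31 indirect, 3 ambiguous of 83 clonotypes
#>   ...

run$calls$direct
#> <expansion_calls> 1084 clonotypes; posterior > 0.95; DE proportion 0.0811
#>   >=  2x: 49 clonotypes
#>   >=  4x: 49 clonotypes
#>   >=  8x: 17 clonotypes
#>   >= 16x: 0 clonotypes
#>   >= 32x: 0 clonotypes

round(run$overlap$matrices[["2"]][1:2, 1:2], 3)
#>        BlL0_1 BlL0_2
#> BlL0_1  1.000  0.996
#> BlL0_2  0.996  1.000

table(truth = merge(scenario$truth, run$classification,
                    by.x = "cdr3_aa", by.y = "key")[, c("label.x", "label.y")])
#>           label.y
#> label.x    ambiguous direct indirect none
#>   direct           0     35        0    0
#>   indirect         3      0       31    1
#>   shared           0      0        0   14
```

Reading: of 1084 clonotypes scored in the direct arm, 49 exceed the 0.95
posterior at ≥2-fold expansion; the two direct-culture replicates become
nearly identical (Morisita–Horn 0.996) once restricted to expanded clones;
pattern discovery then labels the planted direct and indirect carriers
correctly while the clonotypes of "shared" groups — expanded through both
pathways — are deliberately left unassigned.

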