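---
title: "Methods: characterizing directly and indirectly alloreactive TCR-β repertoires"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: characterizing directly and indirectly alloreactive TCR-β repertoires}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(allorep)
```

## Scope and data model

`allorep` analyzes bulk TCR-β clonotype tables from experiments that model
the direct and indirect allorecognition pathways separately (mixed
lymphocyte cultures with allogeneic or lysate-loaded dendritic cells,
vaccination, skin grafting). The unit of analysis is the **clonotype**: a
CDR3 amino-acid sequence (conserved C through conserved F, 1-based
positions over the full loop) with a V-gene attribute, a read count and a
within-sample frequency.

Clonotype identity defaults to the CDR3 amino-acid sequence alone, because
cross-sample matching of expanded clones is done at the amino-acid level;
CDR3+V keying is available everywhere through `key_by_v` for analyses where
convergent recombination across V genes must be kept apart. When rows
collide under a key, counts are summed and the majority V gene is kept
(ties broken lexicographically). Out-of-frame or stop-containing CDR3s
(`_`, `*`) are dropped at read time with a tally — they cannot participate
in any amino-acid-level analysis.

## Normalization

Library composition is corrected with trimmed-mean-of-M-values (TMM)
factors computed from scratch: against a reference sample (chosen as the
sample whose 75th-percentile count-per-total is closest to the mean), each
sample's per-clonotype log2 abundance ratios `M` are doubly trimmed — 30%
of the most extreme `M` and 5% of the most extreme average abundances `A`,
each side — and averaged with inverse asymptotic-variance weights. Factors
are rescaled to geometric mean 1. The estimator agrees with the edgeR
implementation to numerical precision on shared inputs (this is verified in
the test suite, where edgeR serves as an independent oracle); reimplementing
it keeps the normalization semantics explicit and the package's dependency
surface small. Effective library size is total count × factor and is the
abundance denominator everywhere downstream.

A sample sharing no nonzero clonotypes with the reference gets factor 1
with a warning rather than an error: such samples are usually legitimate
(e.g. a technically failed replicate) and excluding them is the caller's
decision.

## Expansion calling

The caller scores, per clonotype, two negative-binomial models of the
counts across samples, with means proportional to effective library size:

* **H0** — one shared relative abundance across stimulated and control
  samples;
* **H1** — separate abundances for the two groups.

Marginal likelihoods are computed by discrete quadrature over an
**empirical prior**: up to 2,000 clonotypes (capped at 10,000) are sampled,
and their moment estimates of abundance (overall for H0, group-wise for H1)
and dispersion form equally weighted prior points; each group in H1
averages over its own group-wise prior independently. The prior
probability of H1 is re-estimated for 10 iterations from the mean
posterior, starting at 0.05 and clamped to [1e-6, 0.5]. The reported
`posterior_de` is P(H1 | data), and the selection rule follows the
posterior-likelihood > 0.95 convention.

Numerical choices:

* **Dispersion** — per-clonotype method-of-moments on counts scaled to a
  common library size, floored at 1e-6 and shrunk 50/50 toward the
  20%-trimmed mean dispersion. With 3–5 replicates per group raw moment
  estimates are extremely noisy; equal-weight shrinkage toward a robust
  common value is the simplest stabilizer that leaves strong signals
  intact.
* **Abundance floors** — group abundances are floored at 0.25 reads per
  group library so that every prior point assigns positive likelihood to
  any observation.
* **Fold estimate** — pooled stimulated over pooled control normalized
  frequency, each side pseudocounted with 0.5 reads
  (`((c_stim + 0.5)/L_stim) / ((c_ctrl + 0.5)/L_ctrl)`). Controls are
  pooled because the experimental designs pool control conditions; the
  pseudocount prevents infinite folds for clonotypes absent from controls.
* **Fold bins** — a clonotype passing the posterior threshold is assigned
  every expansion bin (2, 4, 8, 16, 32) its fold estimate meets, so bins
  are downward-closed by construction and threshold sets are nested.
* The prior subsample is drawn under an explicit seed carried in the
  result object, making calls reproducible.

Validation at the study's conditions (depth 10⁵, 3 vs 3 samples): on null
scenarios the fraction of clonotypes exceeding posterior 0.95 is far below
1%; planted 8× expansions at control frequency ≥ 1e-4 are recovered with
sensitivity 1.0 and no false discoveries (see `scripts/acceptance.R`).

## Overlap

"Morisita's similarity index" is implemented as the **Morisita–Horn**
index on counts — the abundance-weighted variant bounded in [0, 1], which
matches the documented 0 = dissimilar, 1 = similar range (classic Morisita
can exceed 1 on frequency data). `overlap_grid()` restricts each
repertoire to the clonotypes meeting each expansion bin before computing
pairwise indices; a sample with no clonotypes at a bin (common at 16× and
32× in vivo) produces missing cells rather than zeros, because absence of
expanded clones is not evidence of dissimilarity.

## CDR3 similarity graphs

Edges join CDR3s of equal length differing at exactly one position (HD-1).
Construction is by length-bucketed masked-position hashing — each sequence
of length L emits L one-position-masked variants, and any two distinct
sequences colliding on a mask are an HD-1 pair — giving near-linear
behavior instead of all-pairs scanning; the test suite proves edge-set
equality with an O(n²) brute force up to n = 500.

Cluster statistics follow two deliberately different size conventions:
summary statistics (count, max, mean ± SEM) are over clusters of **more
than** `min_size` members (default 5), while the displayed subgraph and
its edges/vertices ratio use **at least** `display_min` members (default
5). Both quoted conventions exist in the repertoire literature; keeping
both configurable lets either be reproduced exactly. The edges/vertices
ratio is computed over the displayed clusters only — isolated vertices are
excluded, since a ratio above 1 (the signature of highly interconnected
alloreactive clusters) is impossible if singletons dominate the
denominator.

## Specificity patterns

Pattern discovery follows the GLIPH2 logic of grouping TCRs predicted to
bind the same peptide-MHC by shared CDR3 features, with fixed, explicit
parameters (all exposed in `run_config()`):

* **Local motifs** — contiguous k-mers, k = 4–7, from the trimmed CDR3
  (3 N-terminal and 2 C-terminal residues removed — the standard
  paratope-region convention that discards the germline-encoded stems).
* **Global templates** — groups of same-length CDR3s identical except at
  one trimmed-region position, recorded with a `%` wildcard.
* **Enrichment** — one-sided Fisher exact test of the member count against
  a reference repertoire; a pattern is reported when support ≥ 3 distinct
  clonotypes, fold ≥ 10 and p ≤ 1e-3. The fold pseudocount (0.5 on the
  reference count) applies only when the reference count is zero.

Pattern identity for the set algebra is the (kind, pattern string) pair.
Patterns found in both the direct and indirect arms have unknown pathway
origin and are excluded from **both** exclusive sets; by default patterns
also present in the unstimulated arm are removed too
(`subtract_unstim = TRUE`), the run records the flag, and both intersection
counts (with and without the unstimulated removal) are reported in
`pattern_sets$counts`. The same exclusion is extended to clonotype level:
a CDR3 matching patterns of both arms is labeled `ambiguous` and dropped
from both labeled sets, with the count reported.

In `run_pipeline()` every arm — including the unstimulated one — is tested
against the same enrichment reference, which defaults to the full pooled
control repertoire (the unstimulated *arm* being its most abundant subset,
1,500 clonotypes by default). Under this default the unstimulated arm can
only report motifs genuinely concentrated among abundant control
clonotypes, i.e. convergent public expansions; with a supplied
`naive_reference` (clonotypes of unrelated naive animals) it behaves
exactly like the stimulated arms. A support-only mode
(`discover_patterns(enrich = FALSE)`) exists for exploratory use but is
not part of the pipeline: on realistic data it reports every trivially
shared k-mer and would empty the exclusive sets through the subtraction
step.

## Repertoire features

* **Frequency statistics** compare labeled clonotypes against the whole
  repertoire restricted by the same 2× expansion threshold that produced
  the labels — without that restriction the comparison would mix the
  expansion effect into the labeling effect. The Mann–Whitney test runs on
  log10 frequencies, exact for small tie-free samples and
  normal-approximated with tie correction otherwise (the `wilcox.test()`
  defaults).
* **V usage and positional profiles** default to clonotype weighting (each
  clonotype once), matching statements phrased in numbers of clones; read
  weighting is available as an option. Cosine similarity is computed on
  usage vectors aligned over a fixed shared gene ordering, with unknown
  genes pooled into `other`.
* **Spectratype** counts distinct clonotypes per CDR3 length and reports
  the ratio of clonotypes longer than 14 aa to those of at most 14 aa —
  the split at which directly alloreactive repertoires show a sharp
  depletion of long loops.
* **Positional profiles** are per-position amino-acid relative frequencies
  for clonotypes of one exact length (default 14, the modal mouse TRB
  length), rows summing to 1.

## Annotation

Specificity databases (VDJdb export TSV, McPAS-TCR CSV, or a generic TSV)
are mapped to a uniform record schema and matched by exact, case-sensitive
CDR3 amino-acid identity — consistent with the small matched shares such
annotation yields. Host-species filtering is off by default because
cross-species CDR3 matches (mouse queries against human-dominated
databases) are usually intended; the flag is recorded when used. A
clonotype matching records of several pathologies contributes once to the
matched share and once to each pathology bucket.

## The synthetic generator

`simulation_spec()` fixes the study conditions the package is validated
under. The generator emulates:

* a background of unique CDR3s (`CASS` prefix, interiors from a fixed
  glycine/serine-rich amino-acid profile, `QYF` suffix; lengths 9–20
  centered at 14) with Zipf-distributed base clone sizes (exponent 1.1);
* ~20 mouse TRBV genes with a fixed baseline usage;
* planted specificity groups: each gets a random interior motif (length
  4–6) inserted at a random offset into 5 carrier CDR3s, plus 2 HD-1
  variants of a carrier mutated outside the motif span — so groups carry
  both a shared local motif and a connected HD-1 cluster seed;
* pathway structure: direct groups expand in direct-stimulation
  conditions, indirect groups in indirect ones, shared groups in both
  (the synthetic counterpart of patterns with unknown pathway origin);
  direct carriers use a length distribution shifted 2 aa shorter and
  TRBV31-skewed V genes, indirect carriers TRBV13-1-skewed ones, so the
  downstream spectratype and V-usage contrasts have a planted direction;
* carriers at baseline frequency U(1e-4, 1e-3), expansion factor 8 (from
  the 2–32 range bounded by the five observable culture divisions), depth
  10⁵ reads, 3 replicates per condition.

All randomness flows from one spec-level seed through fixed per-stage
offsets (background: seed+1; planting: seed+2; sampling: seed + 1000 +
97·condition + replicate), so any stage can be regenerated independently
and bit-for-bit.

What the generator does **not** emulate — and hence what passing its tests
does not show about real data: V(D)J recombination statistics and
insertion/deletion structure, convergent public clusters in unstimulated
repertoires, sequencing error, UMI structure, temporal repertoire skewing
after transplantation, and inter-animal baseline variation beyond
multinomial resampling. Recovery rates on synthetic scenarios are
best-case: planted motifs are uncorrelated with the background, whereas
real repertoires contain confounding public motifs.

## Validation problem sizes

The bundled validation (test suite and `scripts/acceptance.R`) uses: 20
null scenarios of 1,500 clonotypes at depth 10⁵ (3 vs 3) for type-I
control; one 3,000-clonotype scenario with 10 planted 8×-expanded groups
for caller recovery; one scenario with 20 planted motifs (length 4–5) for
discovery recovery; and the default 3,000-clonotype, 12-sample scenario
(10 direct + 10 indirect + 3 shared groups) for end-to-end classification.
These sizes give stable rates while keeping a full validation run within a
few minutes on one CPU.

## Design notes and limitations

* The package is library-first: `run_pipeline()` plus `read_manifest()`
  orchestrate the full analysis from R, and `write_scenario()` /
  `read_manifest()` round-trip datasets through AIRR TSVs and a YAML
  manifest. No shell entry point is shipped — the intended users drive the
  analysis from R, as with the ecosystem this package sits in.
* A condition participating in both arms (e.g. transplantation) is handled
  by pattern assignment alone: its clonotypes end up direct or indirect
  according to the exclusive pattern they match, which is the only
  mechanism the two-arm design offers.
* Whether printed interconnectedness ratios include isolated vertices, and
  whether clonotypes were keyed with or without V genes, are genuinely
  underdetermined conventions; both are configurable and the defaults are
  documented above.
* Hamming distance 1 is exact substitution only — no BLOSUM-weighted or
  indel-tolerant similarity. Fuzzy database matching is likewise out of
  scope.
* The expansion caller assumes replicate samples within a group are
  exchangeable draws around a group abundance; per-animal pairing
  information, if present, is not used.
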