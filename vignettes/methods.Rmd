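---
title: "Methods: the NTE screen and the membrane-signature analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the NTE screen and the membrane-signature analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(proteosig)
```

proteosig implements two genome-scale procedures and the synthetic
ground-truth generators needed to validate them:

1. an **N-terminal extension (NTE) screen** that finds proteins carrying a
   unique N-terminal stretch absent from all of their homologs, and
2. a **membrane-signature analysis** that places whole genomes in a
   two-dimensional space — percentage of transmembrane (TM) proteins
   versus the ratio of Sec signal-peptide calls under two predictor
   regimes — and flags structural outliers against a reference panel.

This vignette documents the statistical and algorithmic choices; the
README shows a worked example.

## 1. The NTE screen

### Homolog search and filtering

For each query protein the screen needs a ranked homolog list. Two routes
are supported and are never mixed within one screen, because raw
alignment scores and BLAST bitscores are not on a comparable scale:

* **Tabular route** — `read_blast_hits()` parses standard 12-column
  tabular output (an optional 13th `ppos` column, when present, supplies
  the similarity operand directly and takes precedence over percent
  identity). Only the best-scoring HSP per query/subject pair is kept and
  self-hits are dropped.
* **Built-in route** — `align_pair()` computes local affine-gap
  (Smith–Waterman/Gotoh) alignments under BLOSUM62 with gap open 11 /
  extend 1, where a gap of length *k* costs open + *k*·extend. Percent
  similarity is the fraction of alignment columns whose substitution
  score is positive; coverage is `(query_end - query_start + 1) /
  query_length`.

`filter_hits()` applies **strict** thresholds — similarity > 30% and
query coverage > 70% — and retains the **top 250** hits by score, with a
lexicographic subject-id tie-break so the retained set is deterministic.
Boundary hits at exactly 30% or 70% are excluded; the tests pin this with
a brute-force oracle.

### Calling an extension

The extension length of a query is the number of residues preceding the
**minimum query start** over its retained hits (`min_start - 1`). Three
guards keep this estimator honest:

* **Support** — at least `min_support = 10` retained hits are required;
  fewer yields status `"insufficient-support"`. With very few homologs a
  single spurious local alignment could dictate the minimum.
* **Anchoring** — only hits that plausibly cover the subject's own
  N-terminus inform the minimum: a hit counts if `subject_start <= 5`
  *or* `query_start <= 5`. The second disjunct keeps full-length matches
  from the query's N-terminus usable even when the *subject* carries its
  own extension (there `subject_start` is large for a reason that says
  nothing about the query). No anchored hit yields
  `"no-anchored-hits"`.
* **Robust minimum (optional)** — `start_quantile` replaces the minimum
  with a lower quantile of anchored starts; the default 0 is the plain
  minimum.

A query is a positive call when the extension length is at least
`min_nte_len = 10`. `max_nte_len` is report-only (sets an `out_of_range`
flag) and `NULL` by default.

### Conservation, families and paralog pairs

Across genomes, `reciprocal_best_hits()` pairs proteins that are mutually
best-scoring (ties broken lexicographically with a classed warning), and
`conservation_scan()` lists, for every positive call, the genomes whose
ortholog also carries a called NTE. Within a hit set,
`cluster_families()` groups proteins into connected components of the
passing-hit graph, and `paralog_nte_pairs()` reports conventional
(extension-free) / NTE-bearing member pairs within each family.

### Amphipathicity of the extension

`annotate_amphipathic()` scores the called extension with the Eisenberg
mean hydrophobic moment over sliding windows of 18 residues at the ideal
helical angle δ = 100°:

$$\mu_H = \frac{1}{N}\left|\sum_{i=1}^{N} H_i\, e^{\,i\,\delta\,\sqrt{-1}}\right|$$

A window is amphipathic when μ~H~ ≥ 0.4 **and** its mean hydrophobicity
is ≤ 0.4 (strongly hydrophobic windows are TM-like, not amphipathic).
18 × 100° is exactly five turns, so the moment is invariant under window
duplication — one of the invariance properties the tests exploit. An
optional secondary-structure annotation restricts scoring to
helix-predicted windows.

### Parameter summary (screen)

| parameter | default | rationale |
|---|---|---|
| `min_similarity_pct` | 30 (strict >) | below ~30% similarity homology is unreliable |
| `min_coverage_pct` | 70 (strict >) | ensures hits span most of the query, so `query_start` reflects a genuine missing N-terminus |
| `top_k` | 250 | caps the hit list at a size where the minimum start is stable |
| `min_support` | 10 | a minimum over fewer hits is dominated by single alignments |
| `min_nte_len` | 10 | shorter leaders are within ordinary start-annotation noise |
| `max_subject_start` | 5 | anchoring tolerance for ragged N-termini |
| `start_quantile` | 0 | plain minimum; raise for robustness to stray local hits |
| moment `window` / `delta_deg` | 18 / 100 | canonical Eisenberg settings; 18 residues = 5 helical turns |
| `mu_threshold` / `h_max` | 0.4 / 0.4 | standard amphipathic-region operating point |

## 2. The membrane-signature analysis

### The census

`genome_signature()` reduces a genome to two coordinates:

* `frac_tm_pct` — percentage of distinct proteins with ≥ 1 predicted TM
  helix;
* `sec_ratio` — ratio of the v5-like to the v4-like Sec signal-peptide
  call percentage. Proteins missing from a prediction table count as
  negative (with a message); a genome with zero v4-like calls gets an
  undefined ratio (`sec_ratio_defined = FALSE`) rather than an infinity,
  and is excluded from ellipse fitting with a warning.

Predictions come either from external files (`read_tm_predictions()`
parses TMHMM-style short format; `read_sp_predictions()` a two-column
summary) or from the built-in rule-based stand-ins below.

### Confidence ellipses and outlier calls

`fit_reference_ellipse()` fits the reference panel with the sample mean
and unbiased sample covariance. Under a bivariate normal, the squared
Mahalanobis distance is χ² with 2 degrees of freedom, so the 95% and
99.9% ellipse boundaries sit at squared radii `qchisq(0.95, 2)` ≈ 5.99
and `qchisq(0.999, 2)` ≈ 13.82. Near-singular covariance (an eigenvalue
at numerical zero) is an error naming the degenerate axis.
`classify_genome()` reports each genome's squared Mahalanobis distance,
inside/outside flags per level, and a **strict** percentile of
`frac_tm_pct` against the reference (fraction of reference genomes
strictly below). Coverage calibration — that ~95% / ~99.9% of draws from
the fitted model fall inside their ellipses — is verified in the test
suite on 10,000 draws.

### Rule-based predictor stand-ins

When external predictions are unavailable, `predict_tm()` and
`predict_sp()` provide deterministic, order-independent substitutes
(reported as `predictor = "builtin"`):

* **TM scan** — sliding 19-residue window of mean Kyte–Doolittle
  hydropathy; centers ≥ 1.6 form segments, segments closer than 5
  positions merge, and each reported span is trimmed back to the
  outermost residues that individually meet the threshold (so a planted
  hydrophobic run is reported at its exact coordinates, without window
  overhang).
* **Sec rules** — a protein is called secreted iff (1) the net charge of
  the first 5 residues (K/R = +1, D/E = −1) is ≥ +1, (2) a run of ≥
  `h_min` hydrophobic residues (A, C, F, I, L, M, V, W — positive
  Kyte–Doolittle hydropathy plus tryptophan) occurs in the first 25, and
  (3) a cleavage position with small residues (A, G, S, C, T) at −3/−1
  exists in positions 10–35. The **v4-like** regime requires `h_min =
  10`, the **v5-like** regime `h_min = 8`; everything else is identical,
  so every v4-like call is structurally also a v5-like call and
  `sec_ratio >= 1` holds by construction. This emulates the strictness
  relationship between predictor generations without claiming to
  reproduce either tool.

These stand-ins are intentionally crude: they have no probabilistic
model, no topology prediction, and no organism-specific calibration.
For real analyses, run the external predictors and feed their outputs
through the parsers; the stand-ins exist so the pipeline is exercisable
end to end and so the simulators have a closed loop with known truth.

## 3. Synthetic ground truth

The simulators are first-class, seeded, pure functions (`with_seed()`
restores the caller's RNG state):

* `simulate_family()` — one random ancestral core, members derived by
  independent per-site substitution (no indels, so planted extension
  lengths are exactly recoverable), extensions prepended to designated
  members; extension composition `"random"` or `"amphipathic"` (periodic
  hydrophobic/polar placement at the 100° helical repeat).
* `simulate_proteome()` — background residues are drawn from a **polar
  alphabet** (D, E, K, R, N, Q, S, T, G, H, P) so planted features are
  the only membrane-like signals present. Planted TM proteins get one
  19-residue I/L/V/F segment starting at ≥ 41; planted Sec proteins get a
  charged n-region, an L-A-A–patterned h-region (12 residues for
  v4-planted, 9 for v5-only, recovering the regime split exactly) and an
  S-N-S c-region whose −3/−1 serines satisfy the cleavage rule. The
  h-region pattern keeps the hydrophobic *run* intact while keeping mean
  hydropathy below the TM threshold, so signal peptides never trigger
  the TM scan. Planted counts are `round(rate * n)`, so zero-error mocks
  reproduce planted rates exactly.
* `simulate_panel()` — bivariate-normal background signatures plus
  optional planted outlier rows, grouped and flagged.

## 4. Reproducibility and limitations

Every stochastic step is governed by an explicit seed; pipeline runs
(`run_screen()`, `run_memsig()`) record parameters and metadata in their
JSON reports and are byte-identical on rerun. Known limitations:

* The screen assumes the homolog set shares the query's domain
  architecture; a query fused to an unrelated N-terminal domain would be
  reported as NTE-positive.
* Extension calling trusts start-codon annotation; systematic
  mis-annotation across a clade would masquerade as conservation.
* The bivariate-normal ellipse model is a descriptive reference
  distribution, not a test of normality; percentiles are reported
  alongside for a distribution-free reading.
* The built-in predictors are rule-based substitutes, suitable for
  simulation closure and smoke analyses only.
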