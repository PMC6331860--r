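---
title: "Quantum-inspired similarity searching: model, protocol, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantum-inspired similarity searching: model, protocol, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sqbvs)
```

## The problem

Ligand-based virtual screening ranks a compound library by structural
similarity to a known-active *reference structure*, hoping that high-ranking
compounds share its biological activity. The dominant representation is the
2D count fingerprint: a sparse map from fragment identifiers (e.g. folded
ECFC_4 circular substructures) to occurrence counts, and the dominant score
is the Tanimoto coefficient. This package implements the Standard
Quantum-Based (SQB) alternative: compounds become complex-valued vectors in
a Hilbert space and similarity becomes a quantum projection probability.

## The SQB model

### Embedding

Write $ff_{ij}$ for the count of fragment $i$ in compound $j$, $cf_i$ for
the number of compounds containing fragment $i$, $|c_j|$ for the size of
compound $j$, $|c_{avg}|$ for the average size, and $m$ for the number of
compounds. Every fragment present in a compound contributes one complex
coordinate $x + yi$:

* the **real part** is the global (inverse-frequency) weight
  $$bel_{G.W.}(f_i) = \frac{\log\!\big((m+0.5)/cf_i\big)}{\log(m+1)},$$
  the Okapi-style IDF normalised by collection size — near 1 for rare
  fragments, near 0 for ubiquitous ones;
* the **imaginary part** is one of three technique weights:
  * *technique 1*, the local saturating weight
    $\mathrm{Tech}_1 = \dfrac{ff_{ij}}{ff_{ij} + 0.5 + 1.5\,|c_j|/|c_{avg}|}$,
  * *technique 2*, the local $\times$ global product
    $\mathrm{Tech}_2 = \mathrm{Tech}_1 \times bel_{G.W.}$,
  * *technique 3 (Okapi)*,
    $\mathrm{Tech}_3 = \mathrm{Tech}_2 \times
    \dfrac{\min(ff_{ij}, ff_{ir})}{\max(ff_{ij}, ff_{ir})}$, which further
    rewards fragments whose multiplicity matches the reference structure
    $r$ (and zeroes fragments the reference lacks);
* the **real special case** (`"real"` scheme) keeps only the real part,
  giving a real Hilbert space. We take the literal reading of "special
  case": the global weight on the compound's support with imaginary part
  identically zero. A documented consequence is that this representation
  depends only on which fragments are present, not on their counts.

The constants 0.5 and 1.5 are fixed, inherited from Okapi/BM25 term
weighting; they are not tunable parameters of this package.

### Similarity

A reference with embedding $|r\rangle$ is treated as the pure state
$d = |r\rangle\langle r| / \langle r|r\rangle$; a library compound
$|c\rangle$ as the one-dimensional subspace with projector
$\hat S = |c\rangle\langle c| / \langle c|c\rangle$. The SQB similarity is
the projection probability $\mu = \mathrm{tr}(d\hat S)$, which for rank-1
states reduces algebraically to
$$\mu(r, c) = \frac{|\langle r|c\rangle|^2}{\langle r|r\rangle\,\langle c|c\rangle} \in [0, 1]$$
by Cauchy–Schwarz. The package always evaluates this sparse closed form —
1024-dimensional operators are never materialised; the dense
`pure_density()`/`projector_onto()`/trace route exists as the framework
definition and serves as the brute-force oracle in the test suite, where
both routes are required to agree to $10^{-12}$ on random complex vectors of
dimension at most 8. The Hermitian inner product conjugates the reference
argument; the modulus makes the choice of side immaterial. The general
framework operations (`fragment_distribution()`, `subspace_probability()`,
`density_from_distribution()`) are provided for completeness and testing;
the screening path uses only pure states.

The benchmark coefficient is the continuous Tanimoto
$$S_{K,L} = \frac{\sum_j w_{jk} w_{jl}}{\sum_j w_{jk}^2 + \sum_j w_{jl}^2 - \sum_j w_{jk} w_{jl}},$$
computed on **raw fragment counts** ($w_{ji} = ff_{ij}$) — the standard
benchmark usage for count fingerprints; on 0/1 vectors it reduces exactly to
the binary Tanimoto $|A \cap B| / |A \cup B|$.

### Degenerate inputs

Empty fingerprints produce zero-norm vectors; both similarity coefficients
define the score as 0 in that case (with a warning, or a single up-front
message inside the bulk evaluation) so a screening run never aborts.
Density-operator validity checks use a tolerance of $10^{-9}$.

## The evaluation protocol

`evaluate_screening()` draws a fixed number of reference structures per
activity class (default 10) with a seeded generator, and uses the *same*
references for every similarity method so method columns are directly
comparable. For each reference the remaining library is ranked
(`rank_library()`), and recall — the percentage of the class's actives
retrieved — is measured in the top 1% and top 5% of the ranking
(`recall_at()`). Per-class recall is the mean over the class's references;
no fusion of reference rankings is performed.

Numerical conventions, chosen once and applied everywhere:

* cutoff positions = `round(fraction * N)` half-away-from-zero, floor 1;
* the reference is excluded both from the ranked candidates and from the
  recall denominator (counting a guaranteed self-hit would inflate recall);
* score ties are broken by ascending compound id, so rankings are
  machine-independent;
* per-row "shaded cell" (best-method) counts award every method tied at the
  row maximum (tolerance $10^{-9}$).

`summarize_table()` computes the aggregate rows of a recall table — the
column means and the shaded-cell counts — and accepts any complete
class-by-method matrix, including the published benchmark tables shipped
with the package (`published_recall_table()`).

## Ranking methods with Kendall's W

`kendall_w()` treats each activity class as a judge ranking the methods by
recall (midranks for ties) and computes the tie-corrected coefficient of
concordance
$$W = \frac{12\sum_j R_j^2 - 3m^2 n (n+1)^2}{m^2(n^3 - n) - m\sum_i T_i},
\qquad T_i = \sum_{\text{tie groups}} (t^3 - t),$$
with significance from the chi-square approximation
$\chi^2 = m(n-1)W$ on $n-1$ degrees of freedom. Midranks plus the
$(t^3 - t)$ correction are the standard treatment and reproduce the
published concordance rows exactly; the package reports the p-value but
enforces no threshold. The overall ranking string orders methods by
ascending rank sum and joins exact ties with `"="`; within a tie group the
input column order is kept, since the order inside a tie carries no
information. The test suite cross-checks `kendall_w()` against an
independent implementation (`vegan::kendall.global`) as well as hand-worked
midrank examples.

## The synthetic benchmark generator

Real screening benchmarks (MDDR, MUV, DUD) are large and partly commercial.
`generate_benchmark()` emulates their *statistical shape* so the entire
pipeline is exercisable in seconds: each activity class owns a disjoint set
of `core_size` fragments; an active carries each core fragment with
probability `core_prob`, every compound additionally carries background
fragments (each universe fragment with probability `background_rate`), and
every carried fragment receives a count of $1 + \mathrm{Poisson}(\lambda)$
with dispersion $\lambda$, so count-dependent code paths ($ff > 1$) are
genuinely exercised.

`core_prob` is the diversity dial: `calibrate_diversity()` bisects it (at
most 30 iterations, fixed seed, tolerance ±0.02) until the generated class's
mean pairwise Tanimoto matches a target. The package default
(`default_benchmark_spec()`) is four classes of 40 actives — two calibrated
to diversity ≈ 0.30 (the homogeneous scale of real drug classes) and two to
≈ 0.10 (the heterogeneous scale) — plus 1600 decoys (1:40 per-class
active:decoy ratio) over a 512-fragment universe with background rate 0.02
and count dispersion 0.5. These sizes keep a full five-method evaluation
under a minute on one CPU while leaving ~18 ranked positions inside the top
1%, enough for recall to discriminate between methods.

What the generator does **not** emulate: correlated fragment co-occurrence,
the heavy-tailed fragment-frequency distributions of real chemistry, folding
collisions, or the class compositions of the real benchmarks. Passing tests
on synthetic data therefore demonstrate correctness of the machinery and
qualitative enrichment behaviour, not virtual-screening performance on real
libraries — for the published collections, the shipped recall tables are the
ground truth the aggregation and concordance modules are validated against.

## Design choices in detail

* **Compound size convention.** "Size" of a compound is ambiguous between
  total fragment occurrences and distinct fragments. The default is the sum
  of counts (`size_mode = "total"`), matching document length in the Okapi
  weighting the techniques are modelled on; `"distinct"` is available. The
  switch lives on `corpus_stats()` rather than on the weighting scheme so a
  stats/scheme pair with conflicting conventions cannot be constructed.
* **Reference embedding.** Under techniques 1–2 the reference is weighted
  as an ordinary compound (its own $ff_{ir}$ and $|c_r|$); under the Okapi
  technique its self-comparison factor is $\min/\max = 1$, so its imaginary
  parts reduce to technique-2 weights.
* **Folding.** Fragment ids are arbitrary non-negative integers; folding to
  a fixed width is treated as upstream preprocessing, and duplicate fragment
  keys in an input record are a parse error, never silently summed.
* **Weighted Tanimoto.** `tanimoto_continuous()` accepts any non-negative
  vectors, so weighted variants can be explored, but the benchmark method
  token `"tan"` always uses raw counts.

## Limitations

* Only single-reference searches are provided; group fusion (MAX/SUM over
  reference sets) and turbo-similarity variants are out of scope.
* Only pure states and one-dimensional subspaces are used by the screening
  path; mixed-state retrieval models are not implemented.
* The chi-square significance for Kendall's W is an approximation; no exact
  permutation test is offered.
* No chemistry perception: the package consumes fingerprints, it does not
  compute them from structures.
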