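# sqbvs — quantum-inspired similarity searching for virtual screening

`sqbvs` implements the **Standard Quantum-Based (SQB)** similarity method
for ligand-based virtual screening, together with the evaluation protocol
used to benchmark it against the Tanimoto coefficient.

It is aimed at cheminformatics researchers who work with sparse 2D count
fingerprints (ECFC-style fragment→count maps) and want to (a) rank compound
libraries against reference structures with quantum projection-probability
similarity, (b) reproduce the aggregation and concordance statistics of
published recall tables, or (c) stress-test similarity methods on synthetic
benchmarks with controllable class diversity.

## The method in brief

A compound `j` is embedded as a sparse complex vector with one coordinate
per fragment `i` it contains:

* **real part** — the global inverse-frequency weight
  `log((m + 0.5)/cf_i) / log(m + 1)`, where `cf_i` is the number of
  compounds containing the fragment and `m` the library size;
* **imaginary part** — one of three Okapi-style technique weights built
  from the local saturating weight
  `ff_ij / (ff_ij + 0.5 + 1.5 |c_j|/|c_avg|)`: the local weight alone
  (tech 1), local × global (tech 2), or local × global ×
  `min(ff_ij, ff_ir)/max(ff_ij, ff_ir)` relative to the reference structure
  `r` (tech 3, "Okapi"). A real-valued special case (imaginary part ≡ 0)
  gives the SQB-Real method.

Similarity between reference `r` and compound `c` is the quantum projection
probability of the reference's pure state onto the compound's subspace,

```
mu(r, c) = |<r|c>|^2 / (<r|r> <c|c>)   in [0, 1],
```

evaluated in sparse closed form (the dense `tr(d S)` operator route exists
as a test oracle). The benchmark is the continuous Tanimoto coefficient on
raw counts. Screening performance is measured as recall of an activity
class in the top 1% / 5% of the ranking, aggregated over classes (mean rows,
best-cell counts) and compared across methods with the tie-corrected
Kendall coefficient of concordance `W` (chi-square significance,
`X^2 = m(n-1)W`).

## Worked example

Concordance over a published benchmark recall table shipped with the
package (10 MDDR activity classes × 5 methods, top-1% cutoff):

```r
library(sqbvs)
tab <- published_recall_table("mddr_ds2", 0.01)
colnames(tab) <- method_display_labels()[colnames(tab)]
kendall_w(tab)
#> Kendall W = 0.452, chi-square = 18.08 (df = 4), p = 0.0012
#> Ranking: SQB(C./T1) = SQB(C./T3) > SQB(C./T2) > SQB(R.) > TAN
```

`W = 0.452` says the ten classes agree moderately on the method ordering;
the complex-embedding SQB variants (techniques 1 and 3, tied rank sums)
outrank technique 2, the real special case, and Tanimoto, and the
chi-square test (p ≈ 0.001) says this agreement is far from random.

A full screening evaluation on a synthetic benchmark — one homogeneous and
one heterogeneous activity class (40 actives each) against 800 decoys:

```r
spec <- benchmark_spec(
  data.frame(class_id = c("HOM", "HET"),
             n_actives = c(40, 40),
             core_size = c(30, 60),
             core_prob = c(0.8, 0.25)),
  n_decoys = 800, seed = 42)
bench <- generate_benchmark(spec)
res <- evaluate_screening(bench$library, bench$labels,
                          references_per_class = 10, seed = 42)
res[["top1pct"]]
#> Screening evaluation, top 1% cutoff
#>
#>                tan sqb-real sqb-tech1 sqb-tech2 sqb-okapi
#> HOM          23.08    23.08     23.08     23.08     23.08
#> HET          15.64    17.95     18.46     17.95     17.69
#> Mean         19.36    20.51     20.77     20.51     20.38
#> Shaded cells  1.00     1.00      2.00      1.00      1.00
```

Each class row is the mean recall (%) over its ten reference searches: on
the homogeneous class every method saturates the 1% cutoff (all 9 positions
inside the top 1% are actives: 9/39 = 23.08%), while on the heterogeneous
class the SQB
variants retrieve more actives than Tanimoto. The Mean row averages over
classes; Shaded cells counts how often each method attains a row maximum
(ties included).

A command-line wrapper with `screen`, `kendall`, and `simulate` subcommands
is installed at `system.file("cli", "sqbvs.R", package = "sqbvs")`; see
`?sqbvs_cli`.

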