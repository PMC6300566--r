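---
title: "Interactome-pathway mutual enrichment: model, calibration and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Interactome-pathway mutual enrichment: model, calibration and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lisindex)
```

## The question and the model

Lithium inhibits a broad family of magnesium-cofactor enzymes, so its
biological action is best described at the level of networks rather than
single targets. `lisindex` operationalizes one way of asking "which diseases
should be most sensitive to lithium?": measure the *mutual enrichment*
between

* the **interactomes** of lithium-sensitive genes — the neighborhoods of
  seed genes such as GSK3B or the inositol monophosphatases in a
  confidence-weighted protein–protein interaction network (STRING-style
  edge list), and
* **disease-associated pathway gene sets** (KEGG-style GMT collections,
  grouped into diseases by a mapping table).

The pipeline has four statistical stages.

**1. Interactome extraction.** For a seed gene $s$, the interactome is the
set of genes reachable from $s$ within $k \in \{1, 2\}$ hops using only
edges with confidence $\geq c$. The threshold applies to *every* edge of a
path: a second-order neighbor only qualifies if both hops clear $c$. This
matches the semantics of querying a STRING subnetwork at a fixed confidence
cutoff; whether the original analysis thresholded the second hop is not
documented, and we chose the stricter, self-consistent reading. $(c, k)$
can be fixed per seed or tuned automatically so the interactome lands in a
target size window (default 100–600 genes, "a few hundred" — large enough
for stable enrichment statistics, small enough to stay specific). The tuner
prefers lower order, then higher confidence, then size closest to the
window midpoint; an unsatisfiable window returns the closest candidate,
flagged. Near-duplicate interactomes (for example paralogs such as
FBP1/FBP2) are merged when their Jaccard index reaches a threshold; "very
similar" has no published quantitative criterion, so the default 0.8 is a
deliberately conservative operationalization, exposed as a parameter.
Merging is single-linkage and idempotent.

**2. Over-representation.** For an interactome of size $n$ and a pathway of
size $K$ in a universe of $N$ genes, the uncorrected p-value of an overlap
$x$ is the hypergeometric upper tail
$P(X \geq x),\; X \sim \mathrm{Hyper}(N, K, n)$, computed with
`stats::phyper` (log-space internally; exact against subset enumeration to
10 significant digits, which the test suite verifies exhaustively for all
universes up to 12). The universe defaults to the network's node set and
can be widened to the union with all pathway genes (`--universe union`);
the choice shifts every p-value and is therefore an explicit flag rather
than a hidden constant.

**3. Empirical calibration.** Uncorrected p-values from gene-set overlap
tests are not comparable across pathways of different sizes, and repeated
testing inflates discoveries. Both problems are handled by resampling: for
each interactome an ensemble of `n_null` (default 1,000) random gene sets
of the *same size* is drawn from the universe, each pathway gets its own
null distribution of uncorrected p-values, and the empirical p-value is the
fraction of null values **less than or equal to** the observed one. The
"$\leq$" tie rule is taken literally from the source procedure. Empirical
p-values have granularity $1/n_\mathrm{null}$ and can be exactly 0 when no
null set is as enriched as the observation.

**4. Disease scoring.** For disease $d$ with pathways $P_d$, all
interactome $\times$ pathway empirical p-values are combined by geometric
mean,
$$p_\mathrm{mean} = (p_1 p_2 \cdots p_n)^{1/n},$$
after replacing values below a zero floor by the floor (default $10^{-4}$,
one decade below the $10^{-3}$ resolution of 1,000 null sets; when
`n_null` differs the default becomes $1/(10\,n_\mathrm{null})$ to preserve
that intent). The geometric mean lets both strong and weak enrichments
carry weight — a single extreme cell cannot dominate the way it would in
Fisher's product without the floor, and uniform mediocrity is not hidden
the way a minimum would. The **sensitivity index** is $1/p_\mathrm{mean}$;
diseases are ranked by it (ties broken by name for determinism). All
cells contribute, significant or not: restricting to significant pairs is
available for the key-gene stage (`--min-significance`) but is off by
default because the source procedure does not state such a filter.

**Key genes.** For one disease, a gene's cross-section count is the number
of (interactome, pathway) pairs whose intersection contains it — by
construction equal to (#interactomes containing it) × (#disease pathways
containing it). Counts are normalized by the disease's pathway count
(giving fractional values such as 1.33 = 4/3) and summed across diseases;
exports print two decimals but sums are computed unrounded.

## The synthetic world

No public accessions back the original inputs (a specific STRING release,
KEGG pathway exports and a curated bipolar gene list), so the package ships
a generator, `generate_study()`, whose defaults are a fixed stated world:

| parameter | default | why |
|---|---|---|
| genes | 2,000 | large enough that 300-gene sets are "small" against the universe |
| mean degree | 20 | sparse graph; order-2 neighborhoods reach a few hundred genes, matching the tuning window |
| edge confidence | Beta(2, 2) | bounded on [0, 1] with mass spanning the 0.4–0.9 threshold grid |
| pathways | 60 of 20–100 genes | tens-to-hundreds scale of curated pathway collections |
| diseases | 20 of 1–3 pathways | small per-disease pathway groups, as in disease catalogs |
| seeds | 10 | the number of distinct lithium-sensitive entities analyzed |
| planted signal | 2 "nervous" diseases × 3 seeds, fraction 0.5 at confidence 0.9 | see below |

Topology is Erdős–Rényi rather than scale-free: the statistics under test
(hypergeometric tails, resampling calibration, geometric-mean combination)
do not depend on degree-distribution realism, and the binomial edge count
gives an analyzable oracle for the generator itself. Planted signal adds
direct seed→pathway-member edges for chosen (seed, disease) pairs, raising
existing edges to the planted confidence, idempotently. The truth-pair
structure is not dictated by the procedure being emulated, so it is our
design: two planted diseases, each wired to three distinct seeds. With a
single planted seed per disease, one floored cell among ten interactome
rows moves the disease mean by only a factor $\approx 2$, which chance
fluctuations of nineteen unplanted diseases overcome regularly; three
planted rows separate truth from non-truth by $\approx 6$ standard
deviations of a null disease's score, making the ranking-recovery property
(all truth diseases outrank all non-truth diseases in ≥95% of seeds) a
property of the method rather than of luck. Disease pathway groups are
drawn *disjoint* whenever the pathway pool allows (and planted pathways are
never reused for other diseases): if a "null" disease could share a planted
pathway, ranking recovery would be ill-posed. What a green recovery test
does **not** establish: performance on scale-free topology, on overlapping
pathway collections, or at effect sizes weaker than the planted defaults.

All randomness flows from one `master_seed` through fixed per-component
offsets (and a string hash of the interactome name for null ensembles), so
regenerating with the same configuration is bit-identical, two pipeline
runs produce byte-identical TSVs, and the file-staged CLI path equals the
in-memory path exactly.

## Numerical and calibration notes

* **Zeros.** Empirical p = 0 is legitimate output; it is floored only at
  the combination stage. The floor, not the p-value, is what bounds the
  best attainable index ($10^4$ at the default floor).
* **Discreteness of calibration.** The overlap statistic is integer-valued,
  so null uncorrected p-values arrive in ties. With the literal "$\leq$"
  rule the empirical p-value is *superuniform* (conservative, never
  anti-conservative): on an unplanted bundle its mean is ≈0.55 and a
  naive KS test against U(0,1) rejects even though the values are valid.
  The acceptance suite therefore checks calibration as (a) validity —
  $P(\hat p \leq t) \leq t$ up to binomial noise at every grid point — and
  (b) exact uniformity of the tie-randomized placement of the observed
  uncorrected p among its nulls (randomized PIT), which is the standard
  construction for discrete statistics. A `(count+1)/(n+1)` pseudo-count
  variant is available behind a flag but off by default, since the floor
  already handles zeros downstream.
* **Precision.** Result files carry 17 significant digits, so re-reading
  them reproduces doubles exactly; the ranking's `print()` method shows
  p_mean at 4 decimals, mirroring the reference report layout (whose
  printed indices are consistent with rounding only the displayed p_mean).
* **Degenerate inputs.** An isolated seed yields the singleton interactome
  (flagged by the tuner); an interactome disjoint from a pathway gives
  uncorrected and empirical p of 1; empty pathway collections, catalogs and
  gene tables round-trip as headers-only files.

## Limitations

* Gene identifiers are opaque case-sensitive strings; no symbol mapping or
  cross-release harmonization is attempted.
* The reference rankings from the original analysis depend on specific
  STRING/KEGG releases and are not reproducible offline; the acceptance
  targets are therefore the in-report arithmetic identities (row sums and
  index↔p_mean reciprocity) plus the property suite on synthetic data.
* No analytic FDR correction is offered — the resampling *is* the
  correction — and no alternative p-combination methods (Fisher, Stouffer)
  are part of the supported surface.
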