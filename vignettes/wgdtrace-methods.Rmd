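---
title: "Reconstructing paleopolyploidy with wgdtrace: models, parameters and design choices"
author: "wgdtrace authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing paleopolyploidy with wgdtrace}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`wgdtrace` reconstructs ancient whole-genome duplications (WGDs) from gene
orders and sequence homology. The pipeline runs: homolog hits → colinear
(syntenic) blocks → per-anchor Ks (synonymous substitutions per synonymous
site) → mixture decomposition of Ks distributions into event peaks →
lineage rate correction and calibrated dating; and, in parallel, blocks →
colinear depth ratios → subgenome assignment → a multi-genome alignment
table → fractionation statistics (loss-run spectra, sliding-window
retention, the P-index) and gene-tree topology support. A genome-evolution
simulator with exact ground truth exercises every stage.

This vignette records the models, the parameters that matter, and the
choices made where the design was genuinely open.

# Colinear block detection

Blocks are found by max-gap chaining: within each chromosome pair, anchors
(homolog pairs mapped to ordinal gene positions) are chained so that both
coordinates are strictly monotone (increasing for `+`, decreasing on the
second genome for `-`) and consecutive anchors are separated by at most
`max_gap` intervening genes on *each* chromosome independently. The
defaults, `max_gap = 50` and `min_anchors = 4`, are the field-standard
settings for plant paleopolyploidy work.

The chaining objective is anchor count, with ties broken by smaller total
ordinal gap and then by the lexicographically first anchor sequence; the
best chain is extracted, its anchors removed, and the search repeated per
orientation. Two consequences worth knowing:

* The objective is symmetric under exchanging the two genomes, but the
  lexicographic tie rule is directional. On inputs with exactly tied
  chains (same length, same total gap), transposing the comparison can
  pick a different member of the tie. Block summaries (count, sizes, gaps,
  orientations) are transpose-invariant; exact anchor lists are
  transpose-invariant only up to ties.
* For self-comparisons, hits of a gene against itself are dropped and, on
  a chromosome against itself, anchors within `max_gap` of the identity
  diagonal are masked; each unordered pair is represented once. No block
  significance statistic is computed — `min_anchors` is the only filter.

# Ks estimation

Ka/Ks uses the unweighted-pathway Nei–Gojobori estimator on codon
alignments: synonymous site fractions per codon (changes producing a stop
count as nonsynonymous opportunities), averaged over the two sequences;
multi-position codon differences averaged over all minimal substitution
paths with equal weights (steps through stops count as nonsynonymous); and
the Jukes–Cantor correction. Proportions at or above 3/4 are reported as
saturated (`NA` + flag), not as errors. The implementation is a
precomputed 64×64 codon-pair table, so pairwise counting is a vectorized
lookup; the test suite checks it against an independent path-enumeration
oracle.

Codon alignment is protein-guided (global alignment of the translations,
BLOSUM62, gap open 10 / extend 0.5, back-translated) whenever sequence
lengths differ; equal-length in-frame pairs — the simulator's output — are
paired codon-by-codon directly. Alignment scoring constants are
configuration, not contract.

Block Ks medians use finite anchor values only; saturated anchors are
excluded and counted, and an all-saturated block keeps an undefined
median.

# Ks mixtures, rate correction, dating

Event peaks are read from a k-component normal mixture fitted by EM on the
Ks sample restricted to a domain, default (0.02, 2]: below ~0.02 allelic
or assembly noise dominates; above 2 the estimator saturates. Initial
means come from kernel-density modes (Silverman bandwidth; modes below 5%
of the highest density are discarded as numerical wiggles), topped up with
quantiles; EM runs to a 1e-6 log-likelihood tolerance with a 1e-3 floor on
component standard deviations, and `k = "auto"` selects 1..5 by BIC. The
fit is deterministic given the data. Component means are the event peaks;
the component standard deviation is the "±" spread reported with a peak.

Two practical notes. Real (and realistically simulated) Ks samples are
heavier-tailed than a normal component, so BIC sometimes splits one event
into two close components; when the number of events in a comparison is
known (e.g. a genome with exactly one WGD), fitting with that `k` is the
appropriate choice, and the package's own acceptance analyses do so.
Cross-species samples mix the speciation orthologs with any outparalog
layer from older shared WGDs; with close divergence/event ages these merge
into one component and bias the divergence peak slightly upward.

Rate correction addresses lineages with divergent substitution rates. The
model is multiplicative per lineage: anchored on one event shared by all
lineages and observed at per-lineage peaks `mu_i`, the coefficient is
`lambda_i = mu_ref / mu_i` with `lambda_ref = 1`. Corrected values are
`lambda_i * ks` within a genome and `mean(lambda_i, lambda_j) * ks`
between genomes (each lineage contributes half the path). This is the
package's own re-specification of the idea — a single benchmark event and
lineage-constant multipliers — and is not claimed to be identical to any
particular published implementation. Its known approximation: shared
internal branches dilute the recovered terminal-rate ratio toward 1, so
the benchmark event should sit close to the divergence it corrects.

Dating scales linearly against one calibrated event:
`t = ks_corrected / kappa_cal * [T_lo, T_hi]`, rounded to integer Myr.
With the gamma hexaploidy calibrated at 115–130 Mya and a corrected gamma
peak of 1.000, a corrected peak of 1.072 dates to 123–139 Mya and 1.030 to
118–134 Mya.

# Depth ratios, subgenomes, alignment table

The colinear depth of a gene is the number of blocks (at least
`min_anchors` anchors) whose span on that gene's side covers its ordinal.
The depth ratio between two genomes is modal depth versus modal depth,
computed over covered genes only (including zeros would bias ratios under
heavy fractionation) and reported unreduced — tetraploid versus
double-tetraploid descendants read 2:4, not 1:2, because the raw modal
depths carry the event algebra.

Subgenome assignment maps the query fragments covering each reference
chromosome into `m` groups (the event multiplicity) by greedy interval
partitioning — no group may overlap itself on the reference — and ranks
groups by retained-anchor count: highest is the dominant subgenome,
lowest the sensitive one; ties are assigned arbitrarily and flagged. A
warning is raised when more than 5% of reference genes have depth above
`m`, which usually means the multiplicity is wrong.

The alignment table stores one row per reference gene (reference order
preserved) and one column per expected subgenome: first the reference and
its own paralog columns (from self-blocks), then each query's columns.
Absent genes carry the reserved mark `"."`; loss, translocation and
assembly gaps are deliberately not distinguished. The header records the
column arithmetic (e.g. `19=3+2+2+2+2+4+4`). When a query gene is colinear
to several reference paralog regions (inevitable once the reference has
its own WGD), the gene is placed once, in its best event layer — larger
blocks first, then block Ks median closest to the query's expected
ortholog band; a duplicated placement after this gating is an integrity
error. On simulations without translocations and with a single-copy
reference, absence marks per column equal the simulated per-subgenome
losses exactly.

# Fractionation statistics

Loss runs are maximal stretches of consecutive absence marks along the
reference order, never spanning chromosome boundaries. Run-length spectra
are fitted by the geometric MLE `p_hat = n_runs / total lost genes`
(support starts at 1: a single lost gene is a run), with a chi-square
goodness-of-fit after pooling tail cells to expected counts of at least 5
(df = cells − 2).

Sliding-window retention uses windows of `M = 100` genes advanced by 1
gene within each reference chromosome. A window pair counts as "not
significantly different" when the absolute retention difference is below
0.05 or a two-proportion chi-square test (on retained counts out of M) is
non-significant at 0.05 — the two criteria are also reported separately,
since published summaries conflate them.

The P-index aggregates windowed retention divergence between two
subgenomes A and B. Per window, `d_i = |A_i − B_i| / (0.5 (A_i + B_i))`
(zero when both rates are zero); a window is included iff
`0.1 < d_i < 3`. Each chromosome contributes the absolute mean of
`sign(A_i − B_i)` over its *included* windows — this reading of the
printed denominator ("N_C − δ(N_C)" interpreted as the included-window
count) is the only one that keeps every contribution, and hence the
index, inside [0, 1]; windows with `A_i = B_i` are always excluded, so the
sign is always defined. Chromosomes are weighted by their share of
windows. Note `d_i ≤ 2` by construction, so the upper cutoff of 3 can
never bind; it is kept as configuration because the statistic is
conventionally printed with it. Values above 0.3 diagnose allopolyploidy
(divergent subgenome fractionation); values near 0 indicate
autopolyploid-like balance.

A design fact that matters for interpretation: with step-1 overlapping
windows, the included-window signs are correlated over roughly one window
length, so each chromosome effectively contributes on the order of
`N_C / M` independent sign clusters. For a balanced (auto-like)
tetraploid, the expected per-chromosome contribution is about
`sqrt(2 M / (pi N_C))` — chromosomes must therefore span many windows
before a balanced genome scores clearly below 0.3. The package's
separation study uses 6 chromosomes of 6,000 genes per subgenome
(comparable, in windows per chromosome, to the gene counts of well
assembled plant chromosomes), loss probabilities (0.2, 0.5) for the
biased design and (0.35, 0.35) for the balanced one, and run length
parameter 0.6. At that size the biased design scores essentially 1 and
the balanced design ~0.1–0.25, separating cleanly at the 0.3 threshold
across seeds. Short test chromosomes (a few hundred genes) do *not*
separate: the balanced design then fluctuates above 0.3. This is a
property of the statistic, not of the simulator.

# Gene-tree topology support

Collinearity-defined orthogroups are selected from the alignment table by
per-genome copy-count patterns (at least the required number of non-absent
cells). A paralog pair supports a lineage-specific WGD when it forms an
exclusive clade whose support meets the bootstrap threshold (default 50);
a shared WGD when the two children of the pair's MRCA each hold one
paralog together with a copy from the putatively sharing genome — the
call's support is the minimum of those two clade supports, since rooted
MRCA nodes are frequently unlabeled; anything else is unresolved. Missing
bootstrap labels count as 0 with a warning. Support frequencies are
reported as counts and percentages at two decimals.

Tree inference inside the package is a neighbor-joining stand-in
(Jukes–Cantor distances, column-resampled bootstrap) intended for
simulated data; externally inferred maximum-likelihood trees are
first-class input as newick with bootstrap node labels.

# The simulator

The simulator walks a dated, rooted species tree (branch lengths in Myr)
from an ancestral genome of `n_chromosomes × genes_per_chromosome` genes
with random in-frame CDS. On each branch segment it applies substitutions
targeting `rate × ks_per_myr × Δt` expected synonymous substitutions per
synonymous site; at placed WGD events it duplicates every chromosome into
labelled subgenome copy sets and removes genes in runs.

* **Sequence divergence.** The target Ks is converted to a per-site
  change probability by inverting the Jukes–Cantor correction; each codon
  position then mutates to a random synonymous alternative with
  probability `ps ×` (its synonymous site fraction), making the expected
  synonymous difference count per codon exactly `ps × s`. Nonsynonymous
  changes (default Ka/Ks 0.3, never creating stops) are applied only to
  codons without a synonymous change in the same pass: mixed codons would
  push the estimator's minimal-path averaging away from the generating
  counts and bias Ks downward by a few percent at Ks ≥ 0.5. With this
  restriction the estimator recovers targets 0.1–1.0 within sampling
  error. Start codons may mutate (nonsynonymously) over deep time; stop
  codons are never created.
* **Rates.** Rate multipliers are keyed by the branch's descendant
  tip/node label; unlisted branches use 1. Event placement is by absolute
  age (`at`, Mya) on a named branch. The recorded truth peak of an event
  for a tip is `2 × ks_per_myr ×` (rate-weighted path length from the
  event to the tip), and divergence truths are recorded per tip pair.
* **Gene loss.** Each copy set loses `round(loss_prob × genes)` genes in
  runs of geometric(`run_p`) consecutive genes (mean run `1/run_p`),
  placed uniformly among valid starts with a one-gene retained buffer on
  both sides (except chromosome ends). The buffer guarantees that ledger
  runs and the loss pattern visible in downstream alignment columns agree
  exactly, and keeps drawn lengths i.i.d. geometric; the final run is
  trimmed to meet the budget. Placement is by rejection sampling (uniform
  over valid starts), with an exhaustive fallback for dense endgames.
* **Not simulated** (by default or at all): translocations, inversions,
  tandem arrays, gene families, selection. Fractionation-plus-
  translocation is therefore observed jointly in real data but only loss
  exists in simulations — which is precisely what makes the
  absence-equality and run-equality checks exact.

What passing simulator-based tests shows, and what it does not: the
statistics are implemented correctly and recover planted truth under the
simulator's assumptions (no rearrangement, clock-like within-branch rates,
geometric loss). Real genomes violate all three to some degree; the
package's thresholds (0.3 for the P-index, 50 for bootstrap support) are
conventions carried from the literature, not quantities validated against
real data here.

# Problem sizes and determinism

The bundled scenario presets default to 2 chromosomes × 300 genes — small
enough for interactive use while preserving every structural property
(depth ratios, table arithmetic, run spectra). The P-index separation
study is the exception (6 × 6,000 genes, 20 seeded replicates per design,
see above). Sequence-evolving analyses in the test suite use 500–1,000
genes per chromosome with 100–150 codons per gene, giving ≥ 1,000 anchor
pairs per Ks sample so that mixture peaks are estimated to ±0.01–0.02.
All randomness flows from a single integer seed per scenario or run; the
same configuration reproduces outputs bit for bit.

# Known limitations

* The rate-correction model assumes lineage-constant multipliers anchored
  to one shared event; rate variation within a branch or benchmark events
  far older than the corrected events degrade it gracefully but
  measurably.
* Cross-species Ks components merge ortholog and outparalog layers when
  event and divergence ages are close; depth-ratio and table layer gating
  mitigate but do not eliminate this.
* The chaining tie rule is directional (see above); all reported
  summaries are tie-invariant.
* `d_i`'s upper cutoff (3) is inert at its default; it is configuration
  kept for convention.
* The NJ + bootstrap tree builder is a stand-in for end-to-end testing,
  not a substitute for maximum-likelihood inference on real sequences.
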