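---
title: "Models and design choices in screenforge"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and design choices in screenforge}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

screenforge implements gene-level hit calling for pooled CRISPRi/CRISPRa
screens and the core analysis stages of CROP-seq perturbation experiments,
together with generative simulators that make every stage testable against
known ground truth. This vignette records the models, the parameters that
matter, and the places where the design was genuinely open and a choice had
to be made.

## The screen phenotype model

A pooled screen reduces to a comparison of sgRNA frequencies between two
samples: t0 versus a final time point (survival/proliferation), or a low
versus a high FACS bin (reporter screens). For sgRNA $i$ with counts
$c_{ia}, c_{ib}$ and sample totals $N_a, N_b$, the raw phenotype is the
depth-normalized log2 frequency change

$$\varphi_i = \log_2\!\left(\frac{c_{ib}+\psi}{N_b}\cdot\frac{N_a}{c_{ia}+\psi}\right),$$

with pseudocount $\psi = 1$ by default (counts are reads, so a unit
pseudocount is a quarter-read perturbation at typical depths; it matters
only for near-zero counts). Phenotypes are centered so the **median over
NTC sgRNAs is exactly zero**. Median centering, rather than mean centering
on the whole library, anchors the null at the non-targeting controls and is
robust to a handful of extreme controls. sgRNAs with fewer than 10 reads in
the reference sample are flagged (`low_count`) but never dropped: silent
filtering changes the gene statistics in ways the user should opt into.

Because both samples are normalized to their totals, phenotypes are
invariant to per-sample sequencing depth, which the suite checks by
rescaling one sample by a constant.

## Gene statistics against a quasi-gene empirical null

Gene-level inference runs every candidate gene and a set of **quasi-genes**
through the identical computation. A quasi-gene is five NTC sgRNA ids drawn
with replacement from the NTC pool; it is what a "gene" looks like when
nothing is true. Three statistics follow:

- **Raw gene phenotype**: the mean of the gene's sgRNA phenotypes. The
  aggregation was an open choice; the mean is the default, and a
  top-$k$-by-magnitude mode ($k=3$) is exposed for users who expect a
  minority of functional guides to carry the signal. Tests pin the mean.
- **$p$-value**: two-sided Mann–Whitney $U$ test of the gene's sgRNA
  phenotypes against *all* NTC phenotypes (not against quasi-gene score
  distributions — the sgRNA-level comparison uses the raw data and is the
  better-powered reading of the procedure; both were considered). The exact
  null distribution of the rank-sum statistic is used whenever the smaller
  group has ≤ 8 values, the larger ≤ 1000 and the data are tie-free —
  which covers the realistic regime of a handful of sgRNAs against an NTC
  pool. We initially reserved exactness for small totals and used the
  tie-corrected, continuity-corrected normal approximation elsewhere, but
  at $n_1 = 5$ the rank-sum distribution is discrete enough that the
  approximation misses exhaustive enumeration by more than 0.01 even at
  moderate $p$; since the exact computation costs well under a millisecond
  at $5$ vs $500$, it is simply used. The approximation remains the
  fallback for ties and for very large groups.
- **Standardized phenotype score**:
  $z_g = (\mathrm{raw}_g - \mathrm{median}(\mathrm{quasi}))/\mathrm{sd}(\mathrm{quasi})$,
  and the **Gene Score** $= z_g \cdot (-\log_{10} p_g)$. By construction
  $p=1$ forces a Gene Score of 0, and the score's sign equals the
  phenotype's.

### The empirical-FDR cutoff

Hits are genes whose Gene Score lies beyond a per-tail cutoff (positive and
negative tails are thresholded separately, since knockdowns that increase
and decrease a phenotype are distinct hit classes). At candidate cutoff $c$
in the positive tail the estimated FDR is

$$\widehat{\mathrm{FDR}}(c) = \frac{\bigl(1 + \#\{\text{quasi} \ge c\}\bigr)
 \cdot n_{\text{genes}}/n_{\text{quasi}}}{\#\{\text{genes} \ge c\}},$$

and the cutoff is the smallest $c$ with
$\widehat{\mathrm{FDR}}(c) \le$ target (default 10%). Two deliberate
departures from the most naive plug-in estimator deserve a record:

1. **The add-one correction.** Without the $+1$, a single gene exceeding
   every quasi-gene yields an estimated FDR of zero and is always called.
   Under a fully null screen the top gene beats the quasi-gene maximum with
   probability roughly $n_{\text{genes}}/(n_{\text{genes}}+n_{\text{quasi}}^{\mathrm{eff}})$
   — a design Monte Carlo put the chance of at least one (guaranteed false)
   hit near one half at balanced counts — so the naive estimator cannot
   control the false-discovery proportion in expectation. The add-one form
   is the standard finite-sample repair for empirical nulls built from
   negative controls; with it, the suite's 200-replicate null simulation
   keeps the mean realized FDP well under the 10% target.
2. **Quasi-gene count = 2 × genes.** The correction sets a floor on the
   discoverable hit-list size: per tail, at least
   $\lceil n_{\text{genes}}/(q \cdot n_{\text{quasi}})\rceil$ genes must
   clear the null before anything is called. With quasi-genes balanced
   1 : 1 to genes at $q = 0.1$, that floor is 10 — too coarse for focused
   screens with few strong hits. Doubling the quasi pool lowers the floor
   to 5 while, in the same design study, keeping the null false-call
   probability at a few percent (more aggressive ratios trade that away:
   the quasi maximum is built from resampled NTCs and cannot explore fresh
   tails the way real genes can, so a large quasi pool paradoxically makes
   single-gene false calls *more* likely by shrinking the floor to 1).
   Both the ratio and the estimator are configurable.

Quasi-gene sampling is seeded explicitly and recorded in the result's
attributes; quasi-gene rows are returned alongside real genes (flagged
`is_quasi`) but are never themselves hits.

## The screen simulators

`simulate_survival_screen()` seeds every library element at `coverage`
cells (default 1,000 — the screens this models are run at roughly
1,000× coverage per element) and grows a cell carrying sgRNA $i$ by
$2^{\,d\,(1 + e_i \gamma_{g(i)})}$ over $d$ population doublings (default
4), where $\gamma$ is the per-gene growth phenotype and $e_i \in [0,1]$ the
per-sgRNA efficacy. Efficacies default to Beta(5, 1): most guides strong,
occasional weak ones, reflecting the knockdown heterogeneity seen between
independent sgRNAs against the same gene. NTCs have $\gamma = 0$ by
construction. Sequencing is multinomial at `depth` reads per sample —
counts sum to depth exactly, and no overdispersion is added by default
because the screens modelled here give no basis for choosing a dispersion;
a larger-variance regime can be emulated by lowering depth.

`simulate_facs_screen()` gives each cell a log-normal reporter whose
log-location is shifted by $e_i \cdot s_{g(i)}$; cells are ranked and the
bottom and top $\lfloor f \cdot n \rfloor$ cells (default $f = 0.30$,
matching bottom-30%/top-30% sorting gates) form the bins, ties broken by
cell index so the gating is deterministic. Per-bin sgRNA tallies are then
sequenced multinomially.

One master seed drives three derived substreams (ground truth, reporter,
sequencing), so stages are individually reproducible and a fixed seed gives
bit-identical output.

What the generators deliberately do **not** model: differentiation
bottlenecks, sort-instrument noise beyond the log-normal reporter, PCR
jackpotting/overdispersion, sgRNA off-target effects, or correlated
guide-level artefacts. Passing recovery tests on these simulations
therefore demonstrates that the statistics are implemented correctly and
control what they claim under clean sampling noise — not that real screens
at these depths will behave as cleanly.

## The CROP-seq generator

Per cell: integrations $\sim$ Poisson(`moi`), default 0.10 and constrained
below 0.15 — the low-MOI regime in which most infected cells are singlets;
integrated sgRNAs uniform over the library (default: the 81-element
composition of 39 genes × 2 sgRNAs, one gene with a single guide, plus 4
NTCs). The cell's cluster is drawn from base proportions, multiplicatively
reweighted by the carried gene's `occupancy_effects`; expression is Poisson
over a small panel (39 targets, one distinctive marker per cluster at
8-fold elevation, housekeeping background summing to ~2,000 UMIs/cell),
with the carried target's mean scaled by $(1-\text{knockdown})$, default
0.8. The sgRNA UMI matrix adds Poisson(40) signal per true integration on
top of Poisson(0.2)/sgRNA ambient background — the ambient level is a
simulation choice, not an inference from data. Poisson expression (rather
than negative binomial) keeps every expectation analytic, e.g. the
carrier/non-carrier expression ratio is exactly $1-\text{knockdown}$;
biological overdispersion, batch structure and real cluster transcriptomes
are out of scope, so assignment and occupancy recovery rates measured here
are upper bounds for real data.

## CROP-seq analysis stages

**Singlet assignment** works per cell on log1p UMIs: the top sgRNA's
z-statistic against the background of all other sgRNAs must reach
`z_cutoff` (default 3 — a documented choice; the upstream source for this
style of rule does not print its value) *and* the top raw count must reach
`min_umi` (default 5), while the runner-up — tested identically against the
background excluding the two leaders — must fail. The `min_umi` floor is
what keeps diffuse ambient counts unassignable, standing in for a full
ambient-aware expectation–maximization demultiplexer; cells with two
passing leaders are `ambiguous_multiple`, everything else `no_signal`. A
zero-variance background maps to $z = \infty$ when the candidate exceeds
its mean (the clean-singlet case) and 0 otherwise, so degenerate cells are
decided, not NaN. On default simulations the suite requires ≥ 95% of true
singlets assigned correctly and ≤ 5% of true multiplets assigned at all.

**Knockdown-cell selection** keeps, among a target's assigned cells, those
with normalized target expression *strictly below* the population median.
Normalized means log1p-CPM — raw counts would conflate knockdown with
library-size variation; this was an open point and the normalized reading
is the documented choice. Strictness makes the all-tied population select
nothing rather than an arbitrary half.

**Differential expression** is a Welch $t$-test per gene on log1p-CPM
z-scored across the cells entering the test, knockdown versus NTC cells,
with Bonferroni adjustment (Benjamini–Hochberg by flag) and significance at
adjusted $p < 0.1$. Standardized log1p-CPM serves as the "scaled
expression" input in place of variance-stabilized Pearson residuals; this
is a deliberate simplification — it preserves the standardized-expression,
$t$-test structure while avoiding a heavyweight normalization dependency,
and it is the main reason effect sizes here should be read as standardized
mean differences, not log fold changes. Per-target summaries keep the top
20 DEGs by |effect| only for targets with more than 50 knockdown cells;
smaller targets stay in the full table.

**Cluster occupancy** reports, per gene and cluster, the gene's cluster
proportion divided by the NTC proportion, at gene level by default (a
gene's sgRNAs pooled; sgRNA level by flag). Clusters with zero NTC cells
yield `NA`, never a silent 0; cells without assignment or cluster label are
excluded with a recorded count, and an optional `qc_keep` metadata flag
lets callers drop quality-control failures upstream, since clustering and
QC are consumed as inputs, not computed. **State-proportion tests** are
two-sided Fisher's exact tests; the reported odds ratio is the sample
cross-product ratio, and the test itself is delegated to the standard exact
implementation, checked in the suite against full hypergeometric
enumeration for all margins ≤ 30.

## Numerical and testing conventions

- All randomness flows from explicit integer seeds; derived substream seeds
  stay below $2^{31}$. No function reads wall-clock entropy.
- FASTQ protospacer counting is exact string matching on a fixed trim
  window (default offset 0, protospacer length), with an optional
  Hamming-1 rescue that sends ties to `unmatched`. Real aligner integration
  is out of scope; for error-free synthetic reads exact matching recovers
  generating counts identically, which the suite verifies.
- Empirical-FDR comparisons use a $10^{-9}$ relative slack so that exact
  rational boundaries (e.g. an estimated FDR of exactly the target) are not
  lost to floating-point representation.
- The suite's stochastic checks run at fixed seeds and modest sizes chosen
  to keep the whole run in minutes: the null-FDP property uses 200
  replicates of a 100-gene × 5-sgRNA, 100-NTC screen at depth $10^6$;
  recovery uses 20 seeds of a 50-gene screen with five $\gamma = -1$ genes
  (all one tail, as dropout hits are) and 100 NTCs, and 20 CROP-seq
  simulations of 10,000 cells. Monte-Carlo assertions carry explicit
  standard-error allowances rather than bare point comparisons.

## Known limitations

Multinomial sequencing has no overdispersion knob beyond depth; the
growth model treats doublings as uniform across cells; CROP-seq expression
is Poisson over a toy gene panel, so DEG power on real transcriptomes will
differ; the occupancy statistic is a ratio of proportions without a
confidence interval (pair it with the Fisher test on the underlying
counts); and the assignment rule, while calibrated to the simulated
ambient model, has no explicit contamination estimate the way a full
demultiplexing EM would.
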