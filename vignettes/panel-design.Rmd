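---
title: "Methods: cross-species panel design and model evaluation"
author: "panelign"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cross-species panel design and model evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(panelign)
```

# The problem

Human brain transcriptome consortia summarize late-onset disease biology as
co-expression modules: fixed sets of genes whose expression covaries across
post-mortem samples, annotated with cohort and brain-region provenance and
grouped into consensus clusters (A–E) of modules that recur across studies.
`panelign` addresses two linked tasks around such a catalog:

1. **Panel design** — compress each module into a handful of representative
   genes measurable in the mouse, design a probe pair per gene, and verify
   the assembled panel in silico.
2. **Model evaluation** — quantify how well a mouse model reproduces each
   human module's disease response, by correlating per-gene log fold
   changes across species.

# Gene prioritization

For one module, take the expression submatrix with samples as observations
and module genes as variables, center and unit-scale each gene, and
decompose it by PCA. With component scores $PC_k$ and variance fractions
$ve_k$ (relative to the *total* variance of the standardized submatrix, the
way a PCA's "percentage of variation explained" is usually reported), each
gene receives

$$ s_g = \left| \sum_{k=1}^{5} r_{gk}\, ve_k \right|,
   \qquad r_{gk} = \mathrm{cor}(x_g, PC_k). $$

Five components are retained by default. The absolute value is taken after
summing, so transcripts strongly *anti*-correlated with the dominant
components rank as highly as positively correlated ones; the alternative
reading, summing absolute per-component terms, is implemented as
`variant = "sum_of_abs"` because the aggregation order is a genuine
modeling choice — the two differ only when a gene's component correlations
have mixed signs, and the default is the more conservative signed sum.

Numerical conventions worth stating:

* **Sign convention.** Each component is oriented so that its
  largest-magnitude gene loading is positive. PCA components are defined
  only up to sign; fixing the orientation makes $r_{gk}$ reproducible
  across linear-algebra backends. Scores are invariant either way.
* **Constant genes** cannot be standardized; they are excluded from the
  decomposition and receive score 0 — they carry no information about
  module behavior.
* **Degenerate inputs.** Fewer than 2 usable genes or 3 samples is an
  error, as is an all-constant submatrix.
* **Ties** in the ranking are broken by gene identifier, ascending, so the
  ranking is a total order and panels are byte-reproducible.

Candidates are then filtered to genes with a one-to-one mouse ortholog
whose mean TPM in the B6 whole-brain reference is at least 1 — one TPM
being the customary detectability cutoff for bulk brain RNA-seq — and the
top 5% of each module's *filtered* list is selected (rank → filter →
select; filtering first would let unexpressed genes occupy top-5% slots).
The selection count is `ceiling(fraction * n)`, which guarantees at least
one gene from every nonempty module.

Panel assembly maps selections to mouse gene space, merges duplicates (a
gene chosen by several modules yields one entry annotated with the union of
module ids, carrying its maximum score as a global score), always includes
the housekeeping and drug-target lists, and, if the total exceeds the
770-entry capacity of the target format, drops key entries
lowest-global-score-first. Using the *maximum* score across selecting
modules preserves each module's best representatives under truncation.
Housekeeping genes win category collisions because their role as
normalization references is structural, not biological.

# Probe design

Each target transcript is scanned in 100-nt windows (stride 1 by default —
exhaustive is affordable at panel scale and a stride is exposed for longer
transcripts). A window is rejected outright when it contains:

* any non-canonical base;
* a homopolymer run of 6 or more;
* a **direct repeat** — two disjoint occurrences of an 8-mer; or an
  **inverted repeat** — disjoint occurrences of an 8-mer and its reverse
  complement (a single self-reverse-complementary 8-mer is a 4-bp stem with
  no loop and is not counted).

Hard filters, rather than weighted penalties, keep the design auditable:
each rejected window can be attributed to a specific feature, and the
no-candidate error reports the tally per filter.

Surviving windows are split at the midpoint into two **adjacent,
non-overlapping** probes: probe A occupies the 3' end of the first half
(it *ends* at the midpoint), probe B the 5' end of the second half (it
*starts* there). Anchoring both probes at the midpoint keeps the pair
contiguous for any tuned lengths; tuning each from the outer ends would
open a gap whenever a probe shortens below 50 nt. Each probe is tuned over
lengths 35–50 nt to minimize |Tm − target| with ties going to the shorter
probe (cheaper synthesis, no information lost).

Melting temperatures come from a unified nearest-neighbor DNA/DNA
parameter set with duplex initiation terms, the entropic salt correction
$\Delta S' = \Delta S + 0.368\,(N{-}1)\ln[\mathrm{Na^+}]$ and two-state
melting at $C_T/4$ for non-self-complementary duplexes. Defaults: 50 mM
Na\+, 0.25 µM total strands, Tm target 78 °C — a plausible
hybridization-panel operating point, exposed in `probeDesignConfig()`
because the true assay chemistry is instrument-specific.

Cross-hybridization is scored by exact 12-mer seeding into the rest of the
transcriptome followed by full-length ungapped extension at each
seed-implied offset; the score is the best off-target identity fraction
(1.0 = perfect duplicate elsewhere). Seeded-plus-extension is equivalent,
for ungapped alignments containing a 12-mer exact match, to an exhaustive
alignment scan, and the test suite asserts that equivalence against a
brute-force oracle. Splice-isoform coverage is the fraction of the gene's
isoforms containing the probe's target subsequence verbatim.

Candidates are ranked lexicographically: isoform coverage (descending),
cross-hybridization (ascending), worst per-pair |Tm − target| (ascending),
window start (ascending, as the final deterministic tie-break). The ranked
list also supplies the alternatives used during panel QC.

# In-silico panel QC

Every unordered pair of panel probes is screened for duplex formation: the
best complementary register is found by exhaustive offset scan, and the
longest perfectly complementary stretch is scored with the same
nearest-neighbor model (stretches under 8 nt cannot form a stable duplex
and score a ΔG of 0). A pair conflicts when ΔG37 ≤ −18 kcal/mol or duplex
Tm ≥ 40 °C; both thresholds are configuration, chosen so that only long
complementary islands — the kind that produce assay background — trip
them. Only perfect stretches are scored; a mismatch/loop hybridization DP
would change few calls at these thresholds and would make the screen much
harder to audit.

Conflicts are resolved iteratively and deterministically: pairs are visited
in panel entry order, the member with the worse composite rank key is
replaced by its gene's next-ranked alternative, and the panel is
re-screened, up to `max_rounds`. Replacement never changes the gene set. A
panel whose conflicts cannot be cleared (no alternatives left) raises an
error naming the pairs rather than silently shipping a conflicted design.
The all-pairs scan is made cheap by a lossless prefilter: any complementary
stretch ≥ 8 nt implies a shared complementary 8-mer, so only pairs sharing
one are evaluated.

# Normalization and differential expression

Counts are normalized by dividing every value in a lane by that lane's
geometric mean of the housekeeping counts — after which each lane's
housekeeping geometric mean is exactly 1 — then log2-transformed with a
pseudocount of 1. Zero or negative housekeeping counts are a data error
(they make the geometric mean meaningless), and a zero pseudocount with
zero values is rejected rather than producing −Inf.

Differential expression between two explicit sample groups uses the
difference of group means on the log2 scale and a moderated t-statistic.
Gene-wise pooled variances $s_g^2$ (d residual df) are shrunk toward a
scaled inverse-chi-square prior fitted across genes by method of moments:
under the prior, $s_g^2/s_0^2 \sim F(d, d_0)$, and matching the first two
moments of the observed $s_g^2$ yields $(d_0, s_0^2)$; the posterior
variance $(d\,s_g^2 + d_0 s_0^2)/(d + d_0)$ enters a t-test with $d + d_0$
df. When the dispersion of the gene variances does not exceed pure
chi-square sampling noise the moment solution degenerates to complete
shrinkage ($d_0 = \infty$), and genes with zero observed variance receive
the prior variance. P-values are BH-adjusted across genes. The moment fit
is simple enough to verify by hand; the suite cross-checks the unmoderated
path exactly against the ordinary equal-variance t-test and the moderated
path against limma's ordering.

# The correlation grid

For one module and one mouse contrast, the module's human genes are mapped
through the one-to-one orthology (optionally restricted to panel genes),
per-gene log fold changes present in both contrasts are paired, and
Pearson's r with a two-sided t-transform p-value is computed. Orientation
is fixed: human is case minus control, mouse is model minus age-matched B6.
At least 5 overlapping genes are required (the t-transform needs 3;
5 guards against degenerate p-values); smaller overlaps are *flagged*, not
dropped, so grid dimensions stay predictable — the grid always has
|contrasts| × |modules| rows, ordered by consensus cluster A–E then module
id. The significance mask uses the unadjusted p < 0.05, matching how such
grids are conventionally displayed; a BH-adjusted column is emitted
alongside for responsible reporting.

# Enrichment

Over-representation uses the upper-tail hypergeometric probability
P(X ≥ overlap), with Bonferroni (ranking) and BH columns. Consensus
clusters are annotated by running the enrichment on the cluster's gene
union and emitting terms in Bonferroni order while suppressing any set with
Jaccard ≥ 0.5 against an already-emitted set — "non-overlapping" needs a
quantitative rule, and Jaccard ≥ 0.5 ("shares at least half its genes") is
the natural reading.

GSEA uses the weighted Kolmogorov–Smirnov running sum: genes ordered by
logFC descending, hits add $|logFC|^p / N_R$ (weight p = 1 by default),
misses subtract $1/(N - N_h)$, ES is the extremum. The null comes from
gene-label permutations under a fixed seed — with the small group counts
typical of mouse cohorts, phenotype permutation would have too few distinct
relabelings to be useful, and gene-label permutation is deterministic and
cheap. NES divides ES by the mean |null ES| of the same sign; p-values use
+1 smoothing and are therefore bounded below by 1/(n_perm + 1).

# The synthetic-data generators

The generators define the study conditions under which the package is
exercised; their defaults are fixed once:

* 30 disjoint modules of 100 genes, clusters A–E and cohort/region labels
  assigned round-robin; 50 cases and 50 controls.
* One latent factor per module; case samples shift the factor mean by the
  module's effect size (defaults evenly spaced in [−1, 1] log2 units).
  Gene values are baseline (8) + loading × factor + N(0, 1) noise, floored
  at zero; 20% of each module's genes are "hubs" with loadings in
  [0.8, 1], the rest in [0.2, 0.6]. The true logFC of a gene is
  loading × effect.
* Mouse counts are negative binomial (dispersion 0.1, log2 link, baselines
  uniform on [4, 9] log2 units, 10 + 10 animals per contrast); per-module
  true mouse logFCs are drawn by the bivariate-normal construction
  $m = (\rho\,\tilde h + \sqrt{1-\rho^2}\,z)\,\sigma_m$ so their
  correlation with the human truth equals the planted concordance ρ
  (defaults cycle +0.6 / 0 / −0.6). Ten housekeeping genes have identical
  means in every group and lane.
* Orthology is one-to-one; module median dN/dS levels are evenly spaced
  over [0.05, 0.45] and the fraction of a module's orthologs expressed in
  the B6 reference follows 1.05 − 2.2 × dN/dS plus N(0, 0.03) noise,
  clipped to [0.02, 1] — a strong planted inverse link.
* Transcripts are 250–600 nt (desk-scale; long enough for many windows,
  short enough that exhaustive stride-1 design stays fast), GC 0.5, 1–4
  isoforms with splice-like internal deletions, plus optional planted
  off-target motifs and poly-A islands.

Two generator behaviors deserve a note. The per-gene empirical logFC error
in the human cohort has a *shared* component — all genes in a module ride
the same factor-mean noise, scaled by their loadings — so its magnitude is
$\sqrt{(loading^2+\sigma^2)(1/n_{case}+1/n_{ctrl})}$ rather than the
independent-noise $\sigma\sqrt{1/n_{case}+1/n_{ctrl}}$; tests use the
former band. And the module dN/dS spread is governed by `dnds_range`
directly (collapse the range and all modules share one level), while
`dnds_link_*` controls only the dN/dS → expressed-fraction link.

What passing tests on these generators does **not** show: real modules
overlap and are far larger (hundreds to thousands of genes), real effect
sizes are not factor-structured, real counts have gene-specific dispersion
and batch structure, and real orthology has many-to-many edge cases that
the one-to-one table excludes by construction. The generators validate the
machinery — estimator correctness, calibration, determinism — not field
performance.

# Problem sizes

The test suite runs the full pipeline on 6 modules × 30 genes (about half
a minute end to end) and the recovery properties on 2–3 modules of 60–150
genes over 20 seeds; `scripts/acceptance.R` uses the full default
conditions (30 × 100 genes, ~5,200 transcripts) and completes in a few
minutes on one CPU. These sizes were chosen so that every check runs
comfortably at a desk while keeping each estimate's sampling error well
inside its asserted band.

# Known limitations

* The nearest-neighbor table covers perfect DNA/DNA duplexes only; probe
  QC ignores mismatched/looped hybrids and intra-probe hairpins.
* Cross-hybridization requires an exact 12-mer seed, so off-targets with
  scattered identity below that granularity are invisible (they are also
  poor hybridizers).
* The moderated test assumes independent genes when adjusting p-values;
  co-expression violates that, as it does for any gene-wise FDR.
* The CLI's contrasts are explicit sample sets; there is no covariate or
  interaction modeling.
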