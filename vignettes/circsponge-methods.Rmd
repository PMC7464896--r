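---
title: "circsponge: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{circsponge: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(circsponge)
```

# Scope

`circsponge` implements a circRNAome analysis for matched tumor/normal
RNA-seq cohorts: differential expression of back-splice junction (BSJ)
counts, structural classification of circRNAs against a genome annotation,
canonical miRNA seed-site scanning on circular and linear sequences,
circRNA–mRNA co-expression, three-tier competing-endogenous-RNA ("sponge")
network assembly, and the intersection of patient co-expression with a
knockdown contrast to nominate downstream targets. Because the analysis
logic is the deliverable — not any particular patient dataset — the package
also ships a fully specified synthetic cohort generator with a recorded
ground truth against which every stage is tested.

# The statistical model, stage by stage

## Normalization

A circRNA's abundance proxy is its BSJ read count: a single-point count at
the circular junction. Relative expression is counts per million (CPM),
$\mathrm{cpm}_{fj} = 10^6 \, c_{fj} / \sum_f c_{fj}$, with **no** length
normalization: per-kilobase scaling is undefined for a junction count, which
does not scale with transcript length. All downstream statistics work on
$\log_2(\mathrm{cpm}+1)$.

CPM is a compositional scale: if a large mass fraction of features changes
between conditions, the null features shift apparently in the opposite
direction. This matters for the synthetic world (below) but is negligible
when, as in real circRNAomes, differential species are a tiny fraction of
all detected junctions.

## Paired differential expression

For the tumor-versus-normal contrast with $n$ matched pairs, each feature is
tested by a two-sided one-sample t-test on the per-subject differences
$d_i = \log_2(\mathrm{cpm}_{iT}+1) - \log_2(\mathrm{cpm}_{iN}+1)$. Fold
changes are $\log_2\!\big((\bar{\mathrm{cpm}}_A + c)/(\bar{\mathrm{cpm}}_B +
c)\big)$ with pseudocount $c = 1$ CPM. Degenerate inputs are defined, not
left to chance: all-zero differences give $p = 1$; a consistent nonzero
shift with zero sample variance is tested against a variance floor
$\varepsilon = 10^{-8}$, so it is (correctly) called significant. Features
with zero counts in every sample are dropped with a message before testing.

A dedicated count-model engine with dispersion shrinkage (DESeq2, edgeR)
would be the standard choice on real data; the package deliberately uses a
closed-form test so that its null behaviour is exactly known and testable
(the suite verifies a 5% type-I error rate at $\alpha=0.05$ under null
simulation at $n = 39$ pairs). The knockdown contrast (unpaired, 3 vs 3 by
default) uses Welch's t-test on the same scale.

Multiple testing uses Benjamini–Hochberg throughout; the implementation is
checked against a brute-force $O(n^2)$ step-up oracle. The differential
circRNA (DEC) filter retains $|FC| \ge 2$, $p < 0.05$ **and**
$\mathrm{FDR} < 0.001$ — the raw-p condition is redundant given the FDR
condition but is applied as stated. Knockdown DEGs use $|FC| \ge 1.5$,
$p < 0.05$ with no FDR filter, again as stated.

## Structural classification

A BSJ is stored by the genomic minimum (`acceptor`) and maximum (`donor`) of
the circularized span, with strand kept for sequence extraction. Against the
annotation, the host is the gene whose transcript has exon boundaries
exactly matching acceptor and donor; failing that, the gene with the largest
overlap, breaking ties by lexicographically smallest gene id (the
tie-breaking rule is this package's choice; junction callers do not document
one). Classes: `multi_exonic` (two or more transcript exons fully inside the
span), `single_exonic` (one), `intergenic` (no overlapping gene). A junction
inside a gene that contains no full exon is classed `single_exonic` with a
warning. The mature sequence of an exonic circRNA is the concatenation of
its included exons in transcript order (reverse-complemented on the minus
strand); introns are excluded, matching the exonic circRNA organization
the classification targets.

## Seed-site scanning

Canonical TargetScan-style sites are defined from the miRNA seed
(nucleotides 2–8, 5'→3'). With $\mathrm{rc}(\cdot)$ the reverse complement
in DNA space:

* `7mer-m8` $= \mathrm{rc}(\text{nt 2–8})$
* `7mer-A1` $= \mathrm{rc}(\text{nt 2–7})\,\texttt{A}$
* `8mer` $= \mathrm{rc}(\text{nt 2–8})\,\texttt{A}$
* `6mer` $= \mathrm{rc}(\text{nt 2–7})$ (off by default; the analysis uses
  presence/absence and counts, for which 6mers are too noisy)

Scanning is in the DNA alphabet; RNA input is mapped U→T at the boundary.
Matches of different types describing the same seed pairing (the same 6-nt
seed-core position) are collapsed to the most specific type
(8mer > 7mer-m8 > 7mer-A1 > 6mer). Distinct positions are all counted, even
overlapping ones — the counting rule is "distinct seed positions", and
context scoring, conservation and non-canonical sites are out of scope.

A circRNA is covalently closed, so a site may span the back-splice junction.
The circular scanner extends the linear representation by its own first
$\ell-1$ characters ($\ell$ the longest site length), reports positions
modulo the circle length, flags wrap-around hits `spans_junction`, and
de-duplicates hits at the same mod-length seed position. The suite verifies
exact equality with a brute-force oracle that tests every rotation by
character comparison, on random sequence/miRNA pairs up to 2 kb.

## Co-expression and the three-tier network

Every (differential circRNA, mRNA) pair is tested by Pearson correlation of
$\log_2(\mathrm{cpm}+1)$ across the shared samples (Spearman available by
configuration), with $p$ from
$t = r\sqrt{n-2}/\sqrt{1-r^2}$ against $t_{n-2}$ and BH adjustment over all
tested pairs. Pearson is the default because the analysis it reproduces
reports correlation-coefficient heatmaps without rank language. Two edge
retention modes exist: the default keeps $p < 0.05$; the alternative
(`padj_pos`) keeps $\mathrm{padj} < 0.05 \wedge r > 0$. Both samples of each
subject are used by default; restricting to one condition is a matter of
subsetting the input matrices.

A sponge triplet (circRNA, miRNA, mRNA) is emitted when (i) the pair's edge
is retained with $r > 0$, (ii) the miRNA has **at least two** seed sites in
the circRNA, and (iii) **at least one** site in the mRNA's 3'UTR. The
source description of the site conditions reads as an "or", but a sponge
axis logically requires shared sites at both ends; this package implements
the conjunction for triplet formation and treats the disjunction only as a
miRNA pre-filter. This is a deliberate, documented interpretation. The
triplet count is verified against a brute-force triple loop in the tests.

## Knockdown target intersection

For a knocked-down circRNA, genes with a retained positive edge
($r > 0$) that are significantly **down** after knockdown are called
`positively_regulated`; genes with a retained negative edge that go **up**
are `negatively_regulated`. The two classes are disjoint by construction,
and each call satisfies the sign invariants ($r > 0 \Rightarrow$ kd
$\log_2 FC < 0$, and conversely).

## Small closed forms

Xenograft tumor volume is $\text{length} \times \text{width}^2 \times 0.52$
(mm³; inputs swapped with a warning if width exceeds length), and RNA
stability series are normalized to the $t = 0$ time point.

# The synthetic cohort: what it emulates, and what it does not

`simulate_cohort()` generates the full input set — GTF-convertible
annotation, genome sequence, junction table with per-sample counts, mRNA
counts, miRNAs — plus a recorded truth. Its defaults are the stated world of
the package's tests:

* **Design**: 39 subjects, one tumor and one normal library each (78
  libraries), mirroring a typical matched-pair cohort of this size.
* **Features**: 200 circRNAs over 5-exon gene models (~90% multi-exonic
  spanning exons 2–4, ~5% single-exonic, 5% intergenic, matching the
  structural mix reported for tumor circRNAomes), 450 genes, 20 miRNAs.
* **Counts**: negative-binomial via Gamma–Poisson, dispersion 0.1 for
  patient tissue, with a shared per-subject log-normal factor
  ($\sigma = 1.0$ on the natural-log scale) planting co-expression; library
  size factors are log-uniform on $[0.5, 2]$ so CPM normalization is
  non-trivial. Base means: 20–200 counts for junctions (BSJ reads are
  genuinely rare), 200–2000 for genes. σ = 1.0 reflects the strong
  between-patient heterogeneity of human tumor cohorts and makes the planted
  correlation, not counting noise, the dominant signal — the "noise-light"
  regime the recovery tests assume.
* **Differential circRNAs**: 30 planted at $|\log_2 FC| = 2$ with an exactly
  balanced up/down split. Balance matters: at 200 features, an unbalanced
  4-fold shift in 15% of the mass would move CPM compositionally — an
  artifact of the deliberately small feature space, not of the method (real
  circRNAomes have $10^5$ species of which a few hundred are differential).
* **Correlations**: 20 triplet pairs at planted strength $\rho = 0.9$
  (positive), 200 decoy pairs (random sign) with *no* shared sites — the
  precision challenge for triplet assembly — and 5 negative partners for the
  designated knockdown circRNA. Each gene participates in at most one
  planted pair; host genes track their circRNA's subject factor at
  $\rho_{host} = 0.9$.
* **Sites**: each triplet plants two 8mer sites on the circRNA (one spanning
  the back-splice junction with probability 0.3) and one on the partner's
  3'UTR, spaced at least 10 nt apart. The miRNA set is rejection-sampled so
  no miRNA's seed core can occur inside another planted site, and all
  accidental seed matches in the scanned sequence space are scrubbed by
  iterative point mutation until a full scan re-detects exactly the planted
  structure. One miRNA serves one triplet, so shared-site coincidences
  between decoy pairs cannot arise by construction.
* **Knockdown**: 3 control vs 3 knockdown replicates at dispersion 0.05
  (cell lines are far less dispersed than patient tissue), planted targets
  shifted by $|\log_2 FC| = 2$ in the direction implied by their correlation
  sign.

What the generator does **not** emulate: read-level alignment and junction
calling (junction counts are drawn directly), splice-isoform complexity,
batch effects, GC/length biases, miRNA expression, and any dependence
between the knockdown cell line and the patient cohort beyond the planted
target directions. A green recovery test therefore establishes that the
pipeline's logic recovers structure that is present and detectable — it says
nothing about upstream callers or about cohorts whose signal is weaker than
the planted world.

# Numerical choices

* Pseudocount 1 CPM in fold changes; variance floor $10^{-8}$ in degenerate
  t-tests; $|r| = 1$ maps to $p = 0$.
* BH is computed by the standard step-up; adjusted values are capped at 1
  and returned in input order.
* Coordinates are 0-based half-open internally; GTF I/O converts at the
  boundary (1-based inclusive), and the conversion round-trips exactly.
* Circular scanning errors on circles shorter than the shortest enabled
  site (7 nt); a 7-nt circle is scannable for 7mers.
* Determinism: all randomness flows from one integer seed through a scoped
  RNG (the global RNG stream is saved and restored), and a fixed
  config + seed reproduces every output file byte for byte.

# Known limitations

* The paired t-test on log-CPM is well calibrated but less powerful than
  shrinkage-based count models at small $n$ or low counts.
* Host-gene assignment for junctions that match no exon boundary is a
  documented heuristic; real junction callers use read-level evidence.
* Seed matching covers canonical 6/7/8mer sites only — no supplementary
  pairing, conservation, or accessibility scoring.
* The co-expression map tests all pairs independently; no network-wide
  shrinkage or partial correlation is attempted.
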