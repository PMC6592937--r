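---
title: "Methods: sliding-window m6A peak calling and downstream analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sliding-window m6A peak calling and downstream analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(meripscan)
library(dplyr)
```

## The problem

MeRIP-seq (m6A-seq) fragments polyadenylated RNA to ~150 nt, enriches
N6-methyladenosine-bearing fragments with an anti-m6A antibody (the IP
library), and sequences them alongside a non-enriched input library.
Methylated regions show a local excess of IP coverage over input.
`meripscan` implements a transcript-coordinate sliding-window caller for
this contrast, the downstream comparisons a two-condition knockdown design
needs (peak overlap between conditions, metagene topography, motif
context), and the orthogonal quantifications that usually accompany such a
study: ΔΔCq expression, gene-specific m6A-IP qPCR, and actinomycin-D decay
half-lives.

All analysis happens in *transcript* coordinates: each gene is represented
by its longest isoform, aligned reads are extended to the average fragment
size (150 nt) from their strand-aware 5' end in genomic space, and the
exonic part of each extended read is projected onto the spliced mRNA. This
removes introns from the statistics — a 100-nt window always covers 100 nt
of mature transcript.

## The peak-calling model

For a transcript of length $L$, windows of width 100 nt start every 10 nt
($\lfloor (L-100)/10 \rfloor + 1$ windows; transcripts shorter than 100 nt
get one full-length window). A fragment counts in every window it overlaps
by at least one nucleotide.

Per window the caller computes:

* a one-sided Fisher exact p-value on the 2×2 table
  $[a, c; A - a, C - c]$, where $a, c$ are the window's IP and input
  fragment counts and $A, C$ the gene's totals over retained windows. The
  alternative is IP excess; the exact tail is the hypergeometric
  $P(X \ge a)$.
* the enrichment score $ES = (a \times d)/(b \times c)$, where $b$ and $d$
  are the gene's *median* window counts in IP and input — a median-
  normalised IP:input ratio, so $ES$ is invariant to library-size
  rescaling of either sample.

Windows below $1/20$ of the gene's top window in *both* libraries are
excluded before testing (annotation-edge guard); medians are computed over
all windows, before the exclusion. p-values are adjusted with
Benjamini–Hochberg across all tested windows of the dataset jointly. A
window is *positive* when $q < 0.01$ (strict) and $\log_2 ES \ge 1$
(inclusive). Overlapping positive windows merge into peaks; each peak's
$ES$ is recomputed from the fragment counts over the merged interval
(keeping the gene medians as $b, d$), its summit is the midpoint of the
highest-$ES$ constituent window, and the smallest constituent $q$ is
reported.

### Numerical and boundary choices

* Coordinates are 0-based, half-open everywhere; BED is native, GTF is
  converted on read. Touching intervals (e.g. peaks `[0,100)` and
  `[100,200)`) do not overlap.
* The Fisher table uses gene-level margins and raw integer counts; median
  normalisation feeds only the enrichment score and reporting. Exact tests
  need integers, and gene-level margins match the per-gene normalisation
  the window medians already perform. The test is one-sided because the
  $ES$ filter fixes the direction of interest anyway.
* The p-value is computed directly from the hypergeometric tail
  (`phyper`), vectorised over all windows; the tests verify it against an
  exhaustive binomial-coefficient enumeration for every 2×2 table with
  grand total ≤ 60 (|Δp| ≤ 1e−9) and against `fisher.test`.
* Zero-input windows get a pseudocount of ½ on $a$ and $c$ (only when
  $c = 0$) so $ES$ stays finite. Genes with a zero median or a zero top
  count in either library cannot be normalised and are skipped and logged.
* Isoform-length ties break by lexicographically smallest transcript id;
  summit ties (equal $ES$) take the 5'-most window. Both keep the pipeline
  fully deterministic — there is no randomness anywhere downstream of the
  input reads.
* Junction-spanning extended reads keep only their exonic overlap, merged
  into one transcript interval. Read strand is ignored at counting time:
  the original protocol aligned strand-specifically, but the methods do
  not state strand filtering at the counting step, so counting is
  strand-agnostic here.

## Comparison, metagene, motif

Two peaks are *common* between conditions when they lie on the same gene
and share ≥ 1 nt (no reciprocal-fraction requirement; the source methods
state none). A gene is a common m6A gene if it carries at least one common
peak; otherwise its peaks make it unique to whichever condition calls
them.

The metagene axis splits the standardised mRNA into 10 bins of 5'UTR, 50
of CDS and 40 of 3'UTR. Each peak contributes one count at the bin of its
summit (fractional position within its region, clamped to the region's
last bin); profiles are percentages of usable peaks and sum to 100. Peaks
on transcripts with an empty region (non-coding models) are skipped and
counted. Region proportions aggregate the same summit assignment at region
level.

The motif check is a fixed-string GGACU scan (U/T-insensitive), not
de-novo discovery: occurrence rate per nt under peaks versus the peak-free
remainder of the same transcripts, with a one-sided Fisher p on the
counts. It is a sanity property of the caller's output, not a motif
finder.

## qPCR and decay quantification

* ΔΔCq with amplification efficiency fixed at 2 (no standard-curve
  correction is described for the emulated protocol): technical replicates
  are averaged, $\Delta Cq = Cq_{target} - Cq_{reference}$ per sample,
  fold $= 2^{-\Delta\Delta Cq}$ against a control sample.
* Gene-specific m6A qPCR uses the percent-of-input convention:
  $2^{\,Cq_{input} - Cq_{IP}} / f$ with $f$ the fraction of material saved
  as input (default 0.05 — five percent of fragmented mRNA kept as
  input). The exact normalisation arithmetic is not printed in the
  emulated protocol; percent-of-input is the field's default and a
  ΔCq-relative-to-control view falls out of the optional `control_sample`
  rescaling, which cancels $f$ entirely.
* Decay: least squares through the origin on $\ln(\text{abundance})$
  versus time — the intercept is exact by construction because abundances
  are renormalised to 1 at $t = 0$. $k = -\text{slope}$, half-life
  $= \ln 2 / k$; $k \le 0$ is reported as stable with infinite half-life
  rather than a negative rate. $R^2$ is the uncentred no-intercept
  version, clamped to $[0, 1]$.
* Tumor volume is the caliper formula $d^2 D / 2$ (mm³), kept as a small
  utility with its domain checks ($0 < d \le D$).

## What the simulator states, and what it does not

The generator emulates the statistical structure of a two-condition
(shNC-vs-shFTO-like) MeRIP-seq experiment, with defaults chosen once:

| parameter | default | rationale |
|---|---|---|
| region lengths | 200 / 1200 / 800 nt means (gamma, shape 4; minima 100/300/150) | typical mammalian mRNA architecture |
| fragment / read | 150 / 80 nt | the emulated library design |
| input coverage | 30× | routine MeRIP-seq depth per transcript |
| site enrichment | 8× | a strong methylated site, clearly above the $ES \ge 2$ call threshold |
| sites per gene | 1 | keeps recovery scoring unambiguous |
| knockdown_effect | 4 | a strong demethylase-knockdown response |
| fto_target_fraction | 0.5 | half the sites respond |
| count noise | Poisson (NB dispersion switchable) | keeps the null calibration interpretable |

Input fragments start uniformly along the transcript; IP fragments are
background (input-rate) plus extra fragments whose 150-nt extent covers a
planted site, at rate background × (enrichment − 1). Reads are the 5'-most
80 nt of each fragment, emitted in genomic coordinates; every planted site
carries a literal GGACU. One synthetic chromosome per gene keeps the
coordinate maps auditable; a multi-exon mode (2–4 exons, fixed introns)
exists to exercise the projection code, and its junction reads are emitted
as 5'-anchored contiguous genomic intervals, the way a simple aligner
would report them.

Constitutive sites follow the canonical m6A topography: half the placement
mass in the stop-codon vicinity `[cds_end − 50, cds_end + 150)`, 0.2 in
the 5'UTR, the rest across CDS and 3'UTR, with ≥ 100 nt separation within
a gene. **Responder (demethylase-target) sites are modelled differently**,
because that is what the emulated biology says: while the demethylase is
present (control), its target sites are hypomethylated — enrichment
`enrichment / knockdown_effect` — and knocking it down restores them to
full enrichment (so knockdown = control × knockdown_effect). They are
placed in the UTRs, where the knockdown's methylation gain is reported to
concentrate. An earlier design held responders at full enrichment in both
conditions and merely multiplied them further in the knockdown; both
conditions then called the same saturated site set and the expected
region-proportion shift was zero — the direction-of-effect check would
have measured summit jitter, not biology. With `knockdown_effect = 1` the
two conditions are exchangeable by construction, which is the null world
the calibration tests use.

What a green simulation test does **not** establish: robustness to
non-uniform input coverage (real transcripts have strong 5'/3' coverage
bias), to isoform mis-annotation beyond the 1/20 guard, to PCR
duplication or mappability artefacts, or to replicate-level biological
variance (the emulated design has one IP/input pair per condition, so no
dispersion model is fitted — differential methylation between conditions
is assessed by set overlap, not by a count model).

## Recovery scoring and calibration

A planted site is recovered when a called peak, widened by ±50 nt (half a
window — a benchmark convention, not a protocol value), contains it;
precision is the fraction of peaks whose widened interval contains a
site. At the benchmark settings the caller recovers ≥ 0.9 of 8×-enriched
sites at ≥ 0.9 precision, and with enrichment ≡ 1 the fraction of tested
windows called positive stays at or below the nominal FDR level — both
are asserted by the test suite, along with end-to-end byte-identical
reruns under a fixed seed.

## Known limitations

* Peaks live in transcript coordinates and are not projected back to the
  genome.
* One IP/input pair per condition; no replicate handling or NB dispersion
  modelling.
* The motif check is descriptive; it cannot substitute for de-novo motif
  discovery.
* Strand-agnostic counting slightly overcounts in regions with antisense
  transcription; the synthetic world has none.
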