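---
title: "Methods: G-quadruplex and SSR landscape analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: G-quadruplex and SSR landscape analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(g4landscape)
```

This vignette is the package's account of the science it implements: the
scoring model, the detection and counting rules, the parameters that
matter, what the simulator does and does not emulate, and the numerical
decisions a maintainer would want written down.

## The run-based G4 score

A DNA G-quadruplex needs runs of guanine on one strand. The score used
throughout this package formalises that: every base inside a maximal run
of $k$ consecutive `G` receives $+\min(k, 4)$, every base inside a run of
$k$ consecutive `C` receives $-\min(k, 4)$, and `A`, `T`, `N` receive 0.
The score of a sequence of length $L$ with per-base scores $s_1 \dots
s_L$ is the arithmetic mean $\frac{1}{L}\sum_i s_i \in [-4, 4]$. The sign
says which strand carries the G-richness; the magnitude (reported as
`abs_score`) tracks quadruplex-forming potential. Capping at 4 means a
run of 4+ guanines saturates the evidence a single base can contribute —
one G-quartet layer per position is the most the structure can use.

Two properties are exact and tested: the score is antisymmetric under
reverse complement ($\mathrm{score}(\mathrm{revcomp}(s)) =
-\mathrm{score}(s)$, because G-runs map to C-runs of equal length), and
`N` both scores 0 and breaks runs — a conservative choice that never
invents guanine content in assembly gaps.

```{r}
hunter_score("GGGGGTGTGTACAGACTCCGGAGGGG")
base_scores("GGNGG")
```

## Detection: windows, merging, trimming, shrinking

Detection (`detect_g4()`, `scan_g4()`) slides a window of `window = 25`
bases and nominates every window whose mean per-base score is
`>= threshold` (default `1.2`) for the plus strand. Overlapping or
book-ended nominating windows merge into one maximal region (the union of
their spans). With `trim = TRUE` the merged region is trimmed to the
outermost `G`, and its score recomputed on the extracted subsequence — the
same computation a reader would do on the reported sequence, which keeps
the region table and the motif-family table consistent with each other.

Two non-obvious decisions:

* **Minus-strand regions are defined by reverse complement.** C-rich
  regions on the forward strand are G-rich regions of the reverse
  complement; the detector literally runs the plus-strand algorithm on
  `revcomp(seq)` and mirrors coordinates back. This makes strand symmetry
  exact by construction (tested: detection of a reverse-complemented
  chromosome equals the mirrored detection of the original), which a
  separate C-run code path with its own tie-breaks would not guarantee.
* **Shrinking instead of dropping.** A merged window union can absorb
  diluting flank bases — including stray isolated `G`s in an AT-rich
  flank — so the recomputed mean of the trimmed region can fall below the
  threshold even though every nominating window was above it. Such a
  region is not discarded (the windows are evidence that a strong core
  exists); it is shrunk: repeatedly remove whichever terminal base leaves
  the better-scoring interval, re-trim to `G`, rescore, until the mean is
  back at or above the threshold. The loop gives up (and drops the
  region) below half a window of length, which in practice does not
  occur. Every reported region therefore satisfies
  `abs_score >= threshold`, and same-strand regions never overlap.

The window width and threshold defaults (25, 1.2) are the values commonly
used for genome-wide plant surveys at this scoring scheme; both are
plain arguments. Sequences shorter than the window are scored as a single
whole-sequence window so organelle-scale toy inputs still work.
`threshold` comparisons are `>=` on exact integer window sums divided by
the window width, so boundary scores such as exactly 1.2 qualify without
floating-point surprises.

Region counts everywhere downstream mean *merged regions*, not
qualifying windows — the only definition under which per-kbp densities
are well defined.

## SSR detection and the SSR-G4 link

`find_ssrs()` reports maximal perfect tandem repeats of primitive 1-6 bp
units with MISA's default minima (20 repeats for mononucleotides, 6 for
dinucleotides, 5 for units of 3-6 bp). Primitivity means an `A` run is
reported once as `p1`, never as `AA`; spans cover whole units only, so a
trailing partial unit is excluded — a deterministic convention that keeps
golden coordinates stable. `merge_compound()` groups SSRs separated by at
most 100 bp into compound records (class `"compound"`, excluded from
p-class tallies, members preserved). The reported motif is the unit as it
occurs at the repeat start; `motif_norm` adds the lexicographically
minimal rotation over the unit and its reverse complement, so rotation
families such as `GGA`/`AGG`/`GAG`/`TCC`/... share one key.

A trinucleotide unit can support G4 formation when its tandem repetition
carries guanine runs on one strand, i.e. it holds at least two `G` or two
`C` (`p3_g4_potential()`). `ssr_g4_association()` counts detected G4
regions (either strand) overlapping each SSR span (optionally extended by
a flank) by at least one base, half-open coordinates throughout; total
incidence is symmetric whether counted SSR-first or G4-first.

## Feature regions and strand contexts

From gene models (`parse_gff()`, union of exons and CDS across isoforms,
UTRs taken from the annotation or derived as exon-minus-CDS split by
strand geometry), `derive_region_sets()` builds twelve classes. The TSS
is the strand-aware 5' end of the gene span (with several isoforms, the
5'-most start — one deterministic TSS per gene). `promoterN` is the N bp
immediately upstream (`[t-N, t)` for `+` genes, mirrored for `-`);
`TSS500` is 250 bp each side of the TSS, always 500 bp before clipping.
Intervals are clipped at chromosome ends with a warning; promoters of
neighbouring genes are *not* masked against each other or against gene
bodies, since no masking rule is standard. Intron is gene span minus
exons; intergenic is the chromosome minus merged gene spans — so
exon + intron = gene span and gene + intergenic = chromosome length,
exactly, on every annotation.

A G4 counts once per region class when it overlaps any interval of the
class by ≥ 1 bp; multi-class counting is intentional (a G4 in a CDS also
counts in exon and gene), matching per-class density profiles that are
each computed independently. Strand contexts: `double` counts both
strands; `coding` counts G4s whose G-rich strand equals the linked gene's
strand; `template` the opposite. For any gene-linked class
`template + coding = double`, which is enforced by test. Stranded
contexts are undefined for gene-less classes (intergenic) and error
there.

`density_profile()` crosses classes × contexts × gene sets; for a gene
set, class intervals are first restricted to the set's genes and the
merged total bp recomputed. Densities are `count / (bp / 1000)` (per
kbp).

## Gene sets and enrichment

`classify_deg()` applies the standard screening rule `|log2FC| >= 1` and
`padj <= 0.05`, both boundaries inclusive; a missing adjusted p (the
fingerprint of independent filtering in upstream DE tools) is `nDEG`.
The promoter G4-count classes (`"0"`…`"5"`, `"6+"`) default to the
promoter2000 window — the widest defined upstream window and the
conventional promoter default; the window is an argument because the
choice is not forced. High-G4 gene selection uses a strict bound
(count > 10) on the promoter template strand. Enrichment is the one-sided
hypergeometric upper tail $P[X \ge k]$ with $X \sim
\mathrm{Hypergeom}(N, K, n)$ via `stats::phyper`, BH-corrected across the
tested terms via `stats::p.adjust`; the test suite checks it against full
subset enumeration for every configuration with $N \le 12$. The universe
defaults to all genes with at least one term, standard over-representation
practice. Term annotation itself (e.g. GO assignment) is an input, not
something this package computes.

## What the simulator emulates — and what it does not

`simulate_g4_study()` builds the package's standard desk-scale study: two
500 kb chromosomes of i.i.d. background bases at GC 0.20 (AT-rich, so
background G-runs are rare and planted-feature recovery is measurable
against a quiet floor), 100 planted G4 motifs (a telomeric-repeat tract,
score 36/21 ≈ 1.71, and a 26-mer survey motif, score 1.42; strands drawn
uniformly), 55 planted SSRs across unit lengths 1-4 including the
G4-capable `(GGA)13`, 120 gene models in non-overlapping slots sized so
every gene has room for a full 2 kb promoter, two genes with a `(GGA)13`
repeat planted on the coding strand of their promoter (the
SSR-forms-a-promoter-G4 mechanism scenario), and a DE table with 30
planted up- and 50 planted down-regulated genes (background genes fail
both screening thresholds by construction).

Numerical details that make truth recovery exact: sequence insertions are
mutually non-overlapping with a 50 bp exclusion zone; planted repeats get
guard bases at both flanks (a base that breaks the repeat's periodicity)
so the maximal perfect repeat coincides exactly with the planted span —
without guards, an AT-rich background would stochastically extend planted
`A` or `AT` repeats and shift their maximal coordinates. Gene coordinates
are drawn independently of insertion positions, so planted motifs can
land in any feature region. All randomness flows through R's RNG: a fixed
seed gives byte-identical FASTA/GFF3/TSV output.

What the simulator deliberately does not emulate: Markov or isochore
structure in the background (the false-positive rate is measured, not
assumed), realistic karyotypes or polyploid homeology, transposon-derived
repeats, imperfect/interrupted repeats beyond the compound mechanism, and
expression noise beyond threshold-respecting draws. Passing recovery
tests therefore demonstrates correctness of the detection and counting
machinery under controlled conditions — not calibrated performance on a
real plant genome, where GC structure, repeat families and annotation
error add failure modes the simulation excludes by design.

Problem sizes used by the test suite are the package's chosen study
conditions: the full 1 Mb study for recovery and additivity checks
(recall of planted G4s ≥ 0.95 required, observed 1.0; SSR coordinate
recovery and DE label recovery exact), 60-80 kb single-chromosome specs
for fast unit tests, 1000 random sequences for the exact antisymmetry and
window-oracle properties, and ≤ 500 × 500 interval instances for the
quadratic overlap oracle.

## Pipeline and outputs

`run_pipeline()` chains the stages (G4 scan → SSR scan → association →
regions → summaries → tracks → gene sets → enrichment) from a config list
or YAML file, logs per-stage counts, writes every table with a `#`
provenance header echoing the parameters, and removes partial outputs on
failure so a results directory is never half-written. Binned tracks
(default 10 Mb bins; tests use 10 kb) assign each feature to the bin
containing its start coordinate — the one rule that makes per-bin counts
sum exactly to the totals. GC content excludes `N` from the denominator
everywhere it is reported.

## Known limitations

* The score models sequence potential only: no thermodynamics, loop-type
  classification, RNA G4 folding, or experimental (BG4/ChIP) validation.
* One published worked-example motif row is internally inconsistent with
  plain whole-sequence run scoring; the package does not use it as a
  reference value.
* Promoters are not masked against upstream genes; in dense genomes
  promoter densities can double-count G4s shared with a neighbour's gene
  body (by design, but worth knowing).
* The SSR scanner reports perfect repeats only; imperfect repeats appear
  only through the compound/interruption mechanism.
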