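---
title: "Coverage-based transcriptome annotation: models, parameters, and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coverage-based transcriptome annotation: models, parameters, and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rnannotate)
```

This vignette is the package's own account of the science behind each
detector: the model, its assumptions, the parameters that matter, and the
design choices made where the design was genuinely open. All coordinates
in the package are 1-based and inclusive, and strand is always `+` or
`-`; a single convention everywhere eliminates a whole class of
off-by-one bugs.

## Input model and normalization

The package consumes per-nucleotide, strand-specific coverage
(`coverage_track`), one vector per replicon, strand, and library. Three
library treatments are distinguished: `TEX_plus` (the terminator
exonuclease digested aliquot of a dRNA-seq sample — processed,
5'-monophosphate RNA is degraded, so primary 5' ends are relatively
enriched), `TEX_minus` (the untreated aliquot), and `fragmented`
(conventional RNA-seq after fragmentation, the best signal for transcript
bodies and 3' ends).

TSS/PS detection compares TEX+ against TEX− coverage, which is only
meaningful on a common scale. `normalize_tracks()` applies total-coverage
(library-size) scaling to the mean total over non-empty tracks.
Replicate-aware statistical normalization (TMM or dispersion-based size
factors) is deliberately out of scope: the detectors consume one combined
signal per strand, not per-replicate counts. Normalization is global per
run; per-condition normalization would change enrichment ratios across
conditions and is not the default.

## Transcript detection

A position is expressed when its coverage is *strictly above* the cutoff
(default 5 in normalized coverage units). Maximal expressed runs are
called transcripts after bridging internal sub-cutoff gaps of at most the
tolerance (default 5 nt, absorbing local dips) and dropping runs shorter
than the minimum length (default 20 nt). The defaults are deliberately
permissive; all three are user-settable. Libraries are combined by the
per-position maximum, so a transcript expressed in any condition is
called; a replicate-minimum mode (`combine = "min"`) is available when
reproducibility across libraries should be required. TEX-treated tracks
are excluded from transcript calling by default because exonuclease
digestion depletes transcript bodies and biases 3' coverage.

Gene annotations then extend and merge the raw calls: any two same-strand
calls overlapping one gene are fused, and a call overlapping part of a
gene grows to cover it. The operation is applied to a fixed point, making
it idempotent and monotone (calls only grow or fuse). Merging across
libraries happens before gene-based extension; the reverse order would
make the result depend on the library order.

## TSS and processing-site model

The seven calling parameters (`param_set()`) act on three per-position
statistics computed from a TEX+/TEX− pair in the strand's 5'→3'
orientation:

* step height: `plus(p) − plus(p−1)`
* step factor: `plus(p) / max(plus(p−1), ε)`
* enrichment: `plus(p) / max(minus(p), ε)`

with a pseudo-count ε = 1 guarding the ratios (configurable). A TSS is
called when coverage is at least `base_height` and either the plain
condition (`step_height ≥ height` and `step_factor ≥ factor`) or the
enrichment-relaxed condition (`enrichment ≥ enrichment_factor`, with the
height and factor thresholds lowered by their reductions) holds, plus a
final `enrichment ≥ 1` guard so a position depleted in TEX+ can never
become a TSS. All comparisons use `≥`, so the optimizer's small steps act
predictably. Processing sites are the mirror image: the step is measured
on the TEX− track, enrichment is TEX−/TEX+, and the threshold is
`processing_site_factor`; the `≥ 1` guard is mirrored as well. TSS and PS
calls from the same data are computed independently.

Calls within 3 nt (`cluster_width`) are merged keeping the highest step,
ties going to the 5'-most position — dRNA-seq 5' ends jitter by a few
nucleotides. A site called in any condition is reported, annotated with
all supporting conditions.

Classification windows are conventions from the dRNA-seq literature, not
quantities the model fits: primary/secondary TSSs live within 300 nt
upstream of a gene start (`utr_window`), antisense TSSs within a gene or
100 nt of its boundaries on the opposite strand (`antisense_flank`). One
TSS may carry several classes with respect to different genes; every TSS
receives at least one class (orphan as the fallback).

Evaluation against a curated set matches each call to its nearest curated
position within ±2 nt (greedy nearest-first; each call matches at most
one curated position). TPR is TP over the curated total; the
false-positive rate takes the negative count to be the curated region
length minus the curated positives, so the specificity that corresponds
to it is `1 − FPR`.

## Genetic-algorithm parameter optimization

The optimizer is a seeded hill climb with the incumbent best as the sole
parent — the reproduction step selects the best set, which with one
candidate per move kind per cycle reduces to hill climbing with random
restarts built in via the global move. Each cycle proposes, in order: a
*random* move (all seven parameters resampled uniformly in their ranges),
a *large* move (exactly two parameters resampled), and a *small* move
(one parameter changed by ±0.1, clamped). The invariants
`height_reduction ≤ height` and `factor_reduction ≤ factor` are
re-imposed by clamping the reduction, so a move can drag a reduction
along with its base parameter. Default ranges are [0, 2.5] for the
height-scale parameters and [0, 10] for the factor/enrichment-scale ones,
mirroring the scales of the statistics they threshold.

A candidate replaces the incumbent when at least one of six conditions
holds (see `?decision_replace`): a sensitivity jump of ≥ 0.1; a strict
improvement in both TPR and FPR; a trade of *k* true positives for at
least 5*k* false positives (in either direction); and, for curated sets
of at least 100 sites, small-step conditions with an FPR slack of
5×10⁻⁵. Conditions 3, 4, and 6 accept candidates that are slightly worse
on one axis for a clear gain on the other, which keeps the search
exploring; condition 6 is implemented exactly as printed, including its
directionality. The search stops after `max_runs` evaluations (default
4000) or as soon as an evaluation is perfect (TPR 1, FPR 0) — stopping
early cannot change any earlier decision. Identical seeds give identical
traces, and every trace row records the candidate, its statistics, the
move kind, and the replacement decision, so the whole run can be
replayed and audited.

## Terminator detection

The convergent-pair heuristic considers adjacent gene pairs whose 3' ends
face each other with an inter-gene region of at most 80 nt. The region is
scanned in both orientations (each gene's own 3' side) for an ungapped
hairpin — stem 4–20 nt *per arm* (the printed "4–20 nucleotides" is read
as the arm length; the loop bounds are stated separately in the same
breath), loop 3–10 nt, at most 25% of stem positions unpaired, G·T wobble
counted as paired — followed by a 10 nt window containing more than 5
thymines. `find_hairpins()` reports maximal hairpins (not strictly
contained in a larger accepted footprint); the terminator search
deliberately iterates *all* accepted hairpins instead, because a poly-T
tract pairs with any upstream A-rich stretch and the resulting A:T
super-hairpin would otherwise swallow the tract of a genuine GC-stem
terminator. Stems are ungapped: mismatches count as unpaired, bulges are
not modeled — at stem lengths of 4–20 the mismatch allowance covers the
realistic imperfections without a gapped alignment.

Any candidate — from the heuristic or an external GFF3 list — is
confirmed by coverage: the min/max ratio over the candidate ± 30 nt,
clipped at replicon ends, at most 0.5 (default) in at least one library.
All-zero windows return a ratio of 1 so unexpressed terminators are "not
confirmed" rather than spuriously confirmed. When several confirmed
candidates sit within 300 nt downstream of one gene, only the one with
the lowest drop ratio survives.

## UTRs, operons, and sub-operons

A 5'UTR runs from a gene's primary TSS (secondary TSSs only under
`all_tss = TRUE`) to the base before the gene start, provided TSS and
gene share a transcript; a 3'UTR runs from the base after the 3'-most
gene of a transcript to the confirmed terminator within the transcript,
or else the transcript edge. Both abut their gene exactly by
construction. Operon boundaries equal transcript boundaries — the
transcript is the transcription unit — rather than first-gene-start to
last-gene-end. Internal TSSs that overlap no gene split an operon into
sub-operons, each running from its TSS to the next such TSS (the TSS
itself is the sub-operon 5' boundary) or to the operon end;
`monocistronic + polycistronic = total` always holds.

## sRNA detection

Five origins are distinguished. Transcripts overlapping no same-strand
gene are intergenic (or antisense if a gene overlaps opposite-strand)
candidates; they must begin at a TSS within 3 nt (`tss_tolerance`) of the
transcript 5' edge. Candidates longer than 500 nt have their 3' end
refined to the first coverage drop point (first position below half the
running maximum, scanned 5'→3' — the running-maximum reference keeps a
late secondary peak from masking an early genuine drop) or the first
processing site, whichever is 5'-most: when both anchors exist the
shorter, more defensible candidate wins. UTR-derived candidates follow
their anchor rules: 5'UTR candidates start at a TSS and end at a PS or
drop point; 3'UTR candidates start at a TSS or PS and end at the
transcript edge or a PS; inter-CDS candidates start at a PS. Antisense
candidates are subject to the TSS requirement by default; the flag that
disables the anchor filter lifts it.

Quality filters: length 30–500 nt, origin-appropriate anchor, and a
stable secondary structure. The built-in stability score is the maximum
number of non-crossing Watson-Crick/G·U pairs (minimum loop 3, computed
exactly by dynamic programming in C++) divided by length and negated;
its default cutoff is −0.05 per nt. It is a pseudo-energy on [−0.5, 0],
not kcal/mol: an adapter to RNAfold (`fold_provider_vienna()`) satisfies
the same contract on the thermodynamic scale and needs its own cutoff.
Every filter can be disabled individually, and overlap with a
user-supplied known-sRNA GFF3 bypasses the filters entirely — the
in-package replacement for a homology database lookup. Rejected
candidates are kept with machine-readable reasons.

## sORF detection

CDS-free transcripts and all UTRs are scanned for ORFs of 30–150 bp
(start through stop; whether the printed range includes the stop codon is
ambiguous — it is included here), default start codon ATG with GTG/TTG
available as options. A candidate needs a ribosome-binding site —
Shine-Dalgarno `AGGAGG`, at most one mismatch — whose 3' edge sits 3–15
nt upstream of the start codon, downstream of a TSS. When several TSSs
could govern the transcript, any TSS yielding a valid RBS window is
accepted (the most permissive reading). Detection commutes with reverse
complementation: minus-strand results equal plus-strand results on the
reverse-complemented genome with mirrored coordinates.

## The synthetic-data generator

The generator is first-class code, not a test fixture: it emulates the
coverage shapes the detectors are built for. Genomes are laid out in
blocks of two plus- then two minus-strand genes, guaranteeing convergent
pairs; each convergent gap (60 nt) carries a written-in terminator
(perfect 8 nt GC stem, 4 nt loop, 7 T tract). Each gene or
operon-spaced gene pair gets a transcript with a 20–80 nt 5'UTR and a
20–60 nt 3'UTR (10 nt next to convergent gaps so the coverage drop stays
inside the gap). Planted TSSs carry TEX+ enrichment strengths drawn from
[5, 8] — promoter strength varies in real dRNA-seq, and the lower edge
still clears a five-fold step in the noiseless limit. TEX+ runs at 0.8 of
the plateau inside transcripts (the exonuclease depletes processed RNA,
and this keeps within-transcript TEX+/TEX− enrichment below 1, as
observed in real data), steps up by the planted strength over 30 nt at
each TSS, and drops to 0.2 downstream of each planted PS; TEX− is
enriched eight-fold downstream of PSs; fragmented tracks are plain
plateaus of the depth (default 50). Gaussian noise (sd `noise_sd`,
floored at zero) is added last; the default is noiseless, which is what
the quantitative recovery claims are stated at.

What the generator does *not* emulate: read-level sampling (coverage is
simulated directly, because the detectors consume coverage, not reads),
sequencing-error models, 5' end jitter beyond the cluster width,
overlapping antisense transcription, and expression heterogeneity across
conditions. Passing recovery tests on this data therefore shows the
detectors implement their rules correctly at realistic signal shapes; it
does not certify performance on any particular organism's libraries.
With noise at 10% of depth the planted features are still recovered
fully, but the permissive default thresholds also admit noise-driven TSS
calls and short spurious transcripts — which is precisely why the
parameter optimizer exists: tuned on a curated set, strict parameters
remove the noise calls without losing planted sites.

## Scales and numerical choices

The optimization experiments run the coverage at unit depth (a plateau of
1) so the factor- and enrichment-scale parameters, whose ranges top out
at 10, actually discriminate between planted promoter strengths; at a
depth of 50 every step factor saturates the range and no threshold in
range can reject a true TSS. The test suite and the acceptance script use
a 50 kb genome with 60 planted TSSs for that experiment (training on the
first half, evaluating on the held-out second half) and a 50 kb, 40-gene
simulation for the full-pipeline recovery measurements; a 10 kb
simulation serves as the fast smoke scale. Ratio pseudo-counts (ε = 1),
the zero-max convention of the drop ratio, clipping at replicon ends, and
tie-breaks (highest step wins, then 5'-most; lowest drop ratio wins, then
closest to the gene) are all fixed and documented rather than
data-dependent.

## Known limitations

* Single-replicon detectors (`detect_convergent`, `detect_sorfs`,
  `apply_srna_filters`) operate per genome; the pipeline loops over
  replicons.
* Condition 1 of the replacement rule accepts a ≥ 0.1 sensitivity jump
  regardless of FPR; on extremely noisy data the search can temporarily
  adopt a high-FPR incumbent that conditions 2–4 cannot walk back at
  equal TP. The printed rule is implemented as printed.
* The hairpin model is ungapped; a terminator whose stem requires a
  bulged alignment to satisfy the 25% rule is missed.
* BAM parsing, read alignment, BigWig, homology searches, target
  prediction, and promoter motif discovery are out of scope by design.
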