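---
title: "Characterising promoter-preserving FOS/FOSB rearrangements"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Characterising promoter-preserving FOS/FOSB rearrangements}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The biological model

The rearrangements this package characterises share a distinctive
architecture. In the *FOS* pattern, a somatic structural variant breaks the
gene **inside exon 4**, within a narrow window of roughly 200 bp.
Transcription stays under the native promoter; the partner locus (an intron
of another gene or intergenic sequence) contributes no exons. The chimeric
read-through transcript therefore terminates unusually: a stop codon is met
at or immediately after the junction, and the transcript's 3' end is set by
a **cryptic polyadenylation signal** (`AATAAA`) in the partner sequence,
visible in RNA-seq as a tumour-specific coverage peak that collapses 10–30
bp downstream of the signal. The truncation removes two 3' instability
elements of the message — the major coding region determinant of
instability and the AU-rich element of the 3' UTR — which is the presumed
route to protein overexpression. The *FOSB* pattern is complementary: the
break lies in an **intron** of the 5' partner, whose splice donor is then
skipped so that part of the intron is exonised, and a short non-template
insert (3 nt in the index case) restores the reading frame into *FOSB*
coding sequence — an in-frame fusion. Because a single break point is seen
per gene per sample, the rearrangement is mono-allelic, and its expression
consequence should be visible as allelic imbalance at heterozygous SNPs.

The pipeline encodes each of these observations as a testable operation:
break-end annotation, DNA/RNA reconciliation, fusion-transcript
reconstruction with frame/stop classification, cleavage-site calling from
coverage drops, allele-specific expression, and a rule-based driver screen
that mirrors the study design's "established cancer genes only" filters.

## Coordinate and orientation conventions

All internal coordinates are **0-based half-open**; conversion to the
1-based closed convention of GFF3/VCF happens only in the I/O layer
(`zero_to_one_based()` / `one_to_zero_based()`), so there is a single
audited conversion site. A break end with orientation `retained-left`
retains `[.., pos)`; `retained-right` retains `[pos, ..)`. BEDPE strands
map `+` to retained-left and `-` to retained-right, the emission convention
of common SV callers. A break position exactly at an exon end is therefore
*intronic* — a deterministic tie-break that follows directly from the
half-open convention. One transcript per gene is assumed throughout (the
analysis reasons at gene level); multi-isoform support is out of scope.

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| `polya_motif` | `AATAAA` | – | canonical cleavage/polyadenylation signal; alternative hexamers are deliberately not scanned |
| `drop_window` | 200 | bp | the "surrounding 200 bp" in which the greatest coverage drop is sought |
| `cleavage_offset_min/max` | 10 / 30 | bp | biological distance from signal to cleavage; implemented as a hard search range |
| `norm_scale` | 10³ | – | coverage is divided by the mean per-gene count and multiplied by 10³ |
| `reconciliation_slack` | 10 | bp | RNA aligners place junctions with small offsets; the matching tolerance is exposed because no published value exists |
| `stop_proximity_codons` | 10 | codons | operationalises "stop at or immediately after the break point"; a declared choice, not a published number |
| `peak_fold_threshold` | 5 | fold | operationalises "a clear peak, present only in that tumour sample" |
| `focal_max_span` | 10⁶ | bp | "focal (<1 Mb)", strict `<`, compared against the *segment* span |
| `amp_min_total_cn` | 5 | copies | "at least five copies in diploid genomes", read as total copies |
| `min_base_qual`, `min_map_qual` | 20 / 20 | phred | common ASE-counting defaults; no published values |

## Numerical and design choices

**Coverage drop.** "Greatest drop in coverage in the surrounding 200 bp"
is not defined mathematically in the source analysis; here it is a
two-sided mean difference: for candidate end $c$,
$\mathrm{drop}(c) = \overline{x}_{(c-w,\,c]} - \overline{x}_{(c,\,c+w]}$
with $w = \texttt{drop\_window}/2$, windows clipped at track edges. The
candidate set is every offset 10–30 bp downstream of every motif; ties
break toward the most 5' candidate for determinism. A non-positive maximal
drop returns no call, and "no motif present" is reported distinctly from
"no drop".

**Peak detection.** A sample is flagged when its mean normalised coverage
over the queried region is at least `peak_fold_threshold` times the mean of
the other samples' means, with a background floor of 1 normalised unit in
the denominator to avoid division by near-zero backgrounds. The statistic
is invariant to a common rescaling of all samples. Note a consequence of
using the mean of *all* other samples: when several carriers share a peak,
each inflates the others' background, so detecting multiple carriers at
fold 5 needs a cohort of more than six samples. The pipeline queries the
200 bp immediately downstream of the partner junction.

**Frame classification.** Translation starts at the 5' gene's native start
codon. The first in-frame stop yields
`stop_offset_codons = floor((stop_start − junction)/3)` (negative when the
native stop precedes the junction, e.g. a 3' UTR break — still TRUNCATING,
correctly: the native protein is intact but the instability elements are
lost). `IN_FRAME_FUSION` requires translation to continue more than
`stop_proximity_codons` past the junction; a transcript with no stop before
its end is reported `UNTERMINATED`, distinctly; a break 5' of the start
codon is `NON_CODING`. Classification is invariant under 3' padding beyond
the stop, which is why the pipeline can translate a provisional transcript
extended 1.5 kb past the partner junction before any cleavage site is
known. Exonisation fires only for intronic breaks in the 5' partner
(donor skip); acceptor-side skipping is not modelled, and antisense
fusions are built literally (reverse-complemented partner sequence) and
typically classify TRUNCATING/UNTERMINATED.

**Reconciliation.** A DNA call is kept iff an RNA call matches both break
ends within `reconciliation_slack` with agreeing orientations — both
conditions, positions *and* orientations, are required. Output coordinates
are always the DNA call's (base-pair-resolved assembly is the position
authority). The mono-allelic check — more than one distinct break point
(single-linkage clusters at the same slack) per gene per sample — is a QC
flag, not a filter.

**ASE.** The source analysis names no test statistic; the minimal standard
for single-SNP ASE is used: a two-sided exact binomial test against 0.5 on
informative (ref+alt) reads, Benjamini–Hochberg adjusted across the run's
SNPs. Reference-bias correction is not applied (the synthetic pileups are
unbiased); real-data use would need it. The acceptance suite calibrates
the null at depth 4000, chosen analytically *before* simulation: the exact
test is conservative at low depth because of discreteness (true size
0.033 at depth 50, 0.048 at 4000), and only the high-depth regime can be
expected to sit inside a binomial confidence band around the nominal 0.05.
Power is checked at the biologically relevant setting (mono-allelic
expression, depth 50).

**Driver screen.** "Focal" compares the *segment* span to 1 Mb with strict
`<`; "at least five copies in diploid genomes" is read as total copies
(not copies above ploidy); amplification requires the oncogene fully
contained in the segment ("amplified the intact gene"), while homozygous
deletion requires only overlap — a focal 0-copy segment clipping a tumour
suppressor still disrupts it. Consequence ("deleterious") and hotspot
annotations are consumed as inputs, mirroring the study's use of an
external annotator.

**Interchange formats.** The structural-variant flavour consumed downstream
is not published; BEDPE was chosen as the interchange format, with an
optional 11th column carrying the non-template insert. Coverage is
bedGraph/wiggle; counts, copy-number segments, cancer-gene lists and
pileups are headered TSVs; genotypes are VCF 4.2.

## What the simulator emulates — and what it does not

`make_genome()` emits a 2 × 50 kb genome (GC ≈ 0.5) with four designed
genes: a 4-exon FOS-like gene whose exon-4 break window (offsets 30–230)
lies 5' of two annotated regulatory elements; a FOSB-like coding partner; a
PPP1R10-like 5' partner whose intron 2 begins with 48 bp of frame-neutral,
stop-free sequence so that a 50 bp exonisation plus a `GCC` insert joins
FOSB-like coding sequence in frame; and a generic tumour suppressor.
`AATAAA` is scrubbed from the plus strand everywhere (by substituting C,
which can never create a stop codon) except one planted signal in the
intergenic partner region, whose cleavage offset is drawn uniformly from
10–30 bp per genome. A stop cassette covering all three frames sits at the
fos-partner junction, making the truncating outcome certain, and 12 bp
into the FOSB-like intron 2, bounding the in-frame fusion's reading.

Coverage is Poisson around a piecewise mean: `mean_depth` (default 50,
a realistic RNA depth for a well-expressed gene) over the transcribed
interval, decaying exponentially (rate 1.2/bp, ≈0 within 5 bp) past the
cleavage site so the greatest-drop search is non-trivial; the noiseless
limit is an exact hard cliff. Pileup alt counts are Binomial(depth,
`ase_ratio`), default 0.9 for carriers — strong but not total imbalance,
what a mono-allelic rearrangement with residual wild-type expression would
show. RNA break points are jittered by ≤3 bp against the DNA truth, and
one DNA-only plus one RNA-only decoy are planted per scenario so
reconciliation has something to reject. Copy-number profiles are diploid
unless events are spiked; the default world carries no driver events
besides the fusion itself, mirroring the quiet somatic background of these
tumours.

The simulator does **not** emulate: read-level alignment artefacts (no
FASTQ/BAM), reference bias in allele counts, splice-aware coverage within
genes, negative-binomial overdispersion (the `noise` parameter is reserved
for it), sequencing error, or the mutation burden of real tumours. A green
test therefore establishes the correctness of the analysis logic on its
stated assumptions, not robustness to alignment pathology.

## Known limitations

* One transcript per gene; regulatory elements must lie within a single
  exon to round-trip through GFF3.
* Cleavage calling searches the transcribed strand of the fusion only, and
  only the configured hexamer; `ATTAAA`-class variants are not scanned.
* The polyA stage runs only for non-exonic partner regions (an exonic
  partner, as in the FOSB case, has its own 3' end).
* Cohort positivity counts reconciled rearrangements per gene; FISH itself
  is not modelled.
* The extension-cohort percentage (89% of 55) is the only externally
  printed number the desk-scale pipeline reproduces; per-cohort break-point
  counts from controlled-access tumour data are outside the testable
  surface.
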