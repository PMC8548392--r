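---
title: "Quantifying Cas12f1 editing outcomes from amplicon deep sequencing"
author: "cas12fkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying Cas12f1 editing outcomes from amplicon deep sequencing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cas12fkit)
```

## The analysis problem

Miniature Cas12f1 nucleases (SpCas12f1, AsCas12f1) are compact type V
CRISPR effectors that cleave double-stranded DNA 22–24 bp downstream of a
5' PAM (TTC for SpCas12f1, YTTN for AsCas12f1), leaving staggered ends
with 5' overhangs. Repair of the break leaves insertion/deletion (indel)
scars centred on the cut site. Editing experiments — transfected human
HEK293T cells, biolistically transformed maize embryos, regenerated T0
plants — are read out by targeted amplicon deep sequencing: PCR amplicons
spanning each target site are sequenced and the fraction of reads carrying
cut-site indels measures editing activity.

cas12fkit implements that readout as a reusable pipeline:

1. **Target-site model** (`target_site()`): PAM matching over IUPAC
   classes, protospacer location, the expected cut centre at a
   configurable 22–24 bp offset from the PAM (default 23, the midpoint of
   the observed cleavage range), and a 12-bp analysis window centred on
   it. The guide itself is modelled too: `find_anti_repeat()` locates the
   crRNA:tracrRNA duplex and `assemble_sgRNA()` joins tracrRNA and crRNA
   through a tetranucleotide linker.
2. **On-target quantification** (`call_sample()`): quality trimming,
   semi-global alignment, indel extraction with left-normalisation,
   grouping into indel types, a 30-fold negative-control frequency
   filter, and mutant-read metrics.
3. **Plant zygosity** (`classify_plant()`, `summarize_cohort()`): diploid
   T0 plants sampled by two leaf punches are classified
   homozygous / heterozygous / chimeric / wild-type from their
   mutant-read fractions and dominant alleles.
4. **Off-target screen** (`enumerate_offtargets()`,
   `screen_candidate()`): genome-wide candidate enumeration under
   mismatch+bulge limits and read-level screening of candidate loci.
5. **Synthetic data** (`simulate_amplicon_reads()` and friends): seeded
   generators for every input, with ground-truth manifests, so the whole
   pipeline is testable without the original sequencing archives.

## Read processing and indel calling

**Trimming.** Reads are 3'-trimmed at Phred 13 by the running-sum rule:
the read is cut before the position maximising the accumulated
`threshold − q` from the 3' end (ties cut leftmost); reads shorter than
30 nt afterwards are discarded but counted. The 30 nt floor is a package
choice — short fragments cannot be anchored reliably on a ~150 bp
amplicon.

**Alignment.** Each distinct read sequence is aligned once to the
amplicon by a semi-global affine-gap aligner (read global, amplicon
overhangs free): match +2, mismatch −3, gap open −6, gap extend −1, a gap
of length $k$ costing $6 + k$. These values are package choices exposed
in `align_params()`; the published analysis used an unpublished custom
script. Reads whose fraction of matched bases falls below 60% are counted
unaligned. Traceback prefers diagonal, then deletion, then insertion;
because every gap run is subsequently **left-normalised** (shifted left
while the flanking base equals the last base of the event), all
sequence-equivalent placements collapse to one canonical
`IndelEvent`, so homopolymer deletions are counted as one type no matter
where the aligner put the gap.

**Window filter and type grouping.** Only events touching the 12-bp
window count: deletions by interval overlap, insertions by their
inter-base anchor falling within the window's closed span. Deletions
frequently span the whole window, which is why intersection rather than
containment is the membership rule. Identical normalised events form an
indel *type*.

**The negative-control filter.** A type is accepted as evidence of
double-strand-break repair only if its per-read frequency is at least 30×
its frequency in a matched negative control (a sample transformed without
the guide). Control types never observed receive a 0.5 pseudocount —
otherwise any type novel to the sample would be divided by zero. A read
carrying at least one retained type is a *mutant read*; aligned reads
carrying none are *wild-type* (reads whose only indels are filtered types
are presumed background). Two metrics are reported: the literal
mutant/wild-type ratio and the mutant percentage of aligned reads
(`frequency_pct`, the default display metric, since published editing
frequencies are percentages).

**Control depth matters.** With the 0.5 pseudocount, a type seen $k$
times among $n_s$ aligned sample reads but absent from a control of $n_c$
aligned reads is retained iff $k/n_s \ge 30 \times 0.5/n_c$, i.e.
$n_c \ge 15\, n_s / k$. Detecting *singleton* types — necessary near the
0.1% detection limit at moderate depth — therefore needs a control about
15× deeper than the sample. The pipeline's simulated studies use a deep
pooled control (20× the sample depth by default in `run_pipeline()`) for
detection-limit work, and matched-depth sample/control pairs when the
question is background suppression itself. Both designs are exposed
through `tally_sample()`, which lets one deep control be tallied once and
reused across samples.

## Zygosity classification

Maize is diploid, so a germline heterozygous edit shows ~50% mutant reads
and a homozygous edit ~100%, in *both* leaf punches and with the *same*
dominant allele — the two punches from different leaves are what
separates germline events from coincidental somatic editing. The bands
quantifying "~50%" and "~100%" are 0.35–0.65 and ≥0.85, with wild-type
≤0.05; the ±15% slack absorbs binomial sampling noise and residual
chimerism and is configurable via `zygosity_bands()`. Anything else —
including concordant fractions with discordant alleles — is chimeric.
Punches with fewer than 100 aligned reads make a plant
"insufficient coverage": reported, never counted as edited. Cohort
summaries divide edited (het+hom) plants by called plants, and zygosity
proportions by edited plants.

## Off-target enumeration and screening

Candidate sites are enumerated directly (no external search tool): at
every PAM occurrence on either strand, the spacer is aligned to the
adjacent genomic window (length spacer + `max_bulges`, anchored at the
PAM, distal end free) by a layered DP with unit mismatch and unit gap
costs. Layer $g$ holds the minimum mismatches achievable with exactly
$g$ gaps, so the reported composition is the lexicographically smallest
(bulges, mismatches) — the minimal-distortion reading of a candidate. A
gap on the genome is an RNA bulge (unpaired guide base), a gap on the
guide a DNA bulge (extra genome base); both may fall on the same
sequence. Genomic N never matches. Limits default to 4 mismatches and 2
bulges. The expected cut window of a bulged candidate is measured on the
genome from the PAM end — a stated package choice, since bulges make
guide-measured and genome-measured offsets differ.

Screening follows read-level rules: at least 5 uniquely assigned reads
(uniqueness = alignment score margin ≥10 over any competing locus, a
package substitute for external-mapper uniqueness), mutant fraction
strictly above 20% inside the candidate's 12-bp window, and a clean
control (≤0.5%, tolerating sequencing error rather than demanding a
literal zero).

## What the simulator emulates — and what it does not

`sim_config()` defaults define the study conditions: full-amplicon
single-end reads (study amplicons are short enough that pair merging is
out of scope); per-base substitution error $10^{-3}$; rare 1-bp error
indels at $10^{-4}$ per base; Phred ~37 with a mild 3' decay. True edits
are drawn from a deletion-dominated spectrum (80% deletions, lengths 1–30
weighted toward 2–12, insertions 1–5 nt) placed to overlap the cut
centre, matching the observation that repair outcomes are predominantly
deletions spanning the expected cut site. Plants are simulated as two
punches with the class structure above; chimeric punches draw independent
edit fractions from Uniform(0.05, 0.95) and independent alleles.
`plant_offtargets()` builds genomes with planted sites of exact
(mismatch, bulge) composition, verified in place by the same DP
definition and scrubbed of spurious background candidates.

Not emulated: realistic Illumina error profiles (homopolymer effects,
quality-correlated errors), PCR chimeras and index hopping, UMI
structure, and paired-end merging artefacts. Passing tests demonstrate
the *analysis* is correct under a clean, well-specified error model; they
do not certify performance on pathological real-world libraries. Depths
are package placeholders (the study's per-treatment depths are not
published): simulated studies here use 20 000-read samples for
detection-limit work, 5 000 for background studies, 1 000 per leaf punch,
and a 50 kb genome with 20 planted sites for the off-target check — sizes
at which every statistical check has comfortable power.

## Numerical and degenerate-input choices

* Coordinates are 0-based half-open internally; reports print 1-based
  closed positions.
* `expected_cut_window()` rejects windows extending past the amplicon,
  naming the site.
* An all-zero coverage track yields no enriched species; a zero median
  falls back to a threshold floor of `k` (as if the median were 1 read).
* `frequency_ratio` is 0 when both counts are 0 and `Inf` (flagged
  `saturated`) when wild-type reads are 0 with mutants present.
* Duplicate off-target footprints are deduplicated keeping the smallest
  (bulges, mismatches); ties in the DP keep the shortest genomic
  footprint.
* The wobble-aware duplex score in `find_anti_repeat()` (Watson–Crick 2,
  G:U 1, otherwise −2) is a package invention — the native guide was
  published as a pairing diagram, not a scoring scheme — and the ungapped
  model is a deliberate simplification: internal loops in the natural
  duplex are not modelled.
* sgRNA component order defaults to tracr→linker→repeat→spacer and is
  configurable; the published construct does not state the junction
  order.

## A small worked run

```{r, eval = FALSE}
site <- target_site(amplicon, spacer = "GCTGACGTATGCAATGCTAC", pam = "TTC")
ctl  <- simulate_negative_control(site, sim_config(seed = 2, depth = 40000))
smp  <- simulate_amplicon_reads(site, sim_config(seed = 3, depth = 2000,
                                                 edit_fraction = 0.2))
cs   <- call_sample(smp$reads, site, tally_sample(ctl$reads, site))
summary(cs)
```

The README shows this run with its printed output. `run_pipeline()`
wraps the same stages behind a YAML config and writes TSV/JSON outputs
plus a manifest of thresholds and checksums; `inst/cli/cas12fkit.R` is a
thin command-line wrapper over it.

## Known limitations

* Substitution (base-editing) outcomes are ignored by design; only
  indels are quantified.
* Large rearrangements and indels extending beyond the amplicon cannot
  be observed in this assay model.
* The uniqueness margin is a within-candidate-set notion; it does not
  model genome-wide mappability.
* Zygosity bands assume diploidy; higher ploidies need different bands
  and are out of scope.
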