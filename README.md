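# cas12fkit

Quantifies genome-editing outcomes from targeted amplicon deep sequencing
of miniature Cas12f1 nuclease experiments — the assay used to measure
SpCas12f1/AsCas12f1 activity in human HEK293T cells and maize (*Zea mays*)
T0 plants.

Cas12f1 recognises a 5' PAM (TTC for SpCas12f1, YTTN for AsCas12f1) and
cleaves 22–24 bp downstream, leaving staggered ends whose repair produces
insertion/deletion (indel) scars. The package models the target site and
its expected cut window, calls indels from amplicon reads, classifies
diploid plant zygosity, enumerates and screens off-target sites, and
simulates every input it consumes so the full analysis is testable without
the original sequencing archives.

**Who it is for:** anyone analysing (or simulating) CRISPR amplicon
deep-sequencing experiments in R who needs a transparent, scriptable
alternative to web tools, with a negative-control-aware filter and
plant-cohort summaries.

## The core procedure

For a target site with PAM interval ending at position $e$ on the
amplicon, the expected cut centre is $c = e + \delta$ ($\delta = 23$ by
default, inside the observed 22–24 bp range) and the analysis window is
$[c-6,\, c+6)$. Reads are Phred-13 quality-trimmed (BWA-style running
sum), aligned semi-globally (match +2, mismatch −3, gap open −6, extend
−1), and each gap run becomes a left-normalised indel event. Identical
events form an indel *type*; a type with sample frequency $f_s$ and
control frequency $f_c$ (0.5 pseudocount for unseen control types) is
retained iff

$$ f_s \ge 30 \times f_c . $$

A read carrying a retained type is a mutant read; the package reports both
the literal mutant/wild-type ratio and the mutant percentage of aligned
reads. Diploid T0 plants sampled by two leaf punches are called
homozygous (~100% mutant reads in both punches, same allele),
heterozygous (~50%, same allele), wild-type (background) or chimeric
(anything discordant). Off-target candidates are every genomic site whose
spacer alignment uses at most 4 mismatches and 2 bulges (layered DP at
each PAM occurrence, both strands); candidate loci are putative edits only
with ≥5 uniquely assigned reads, >20% mutant reads in the 12-bp window,
and a clean negative control.

## Worked example

```r
library(cas12fkit)

set.seed(42)
flank5 <- paste0(sample(c("A","C","G","T"), 40, TRUE), collapse = "")
flank3 <- paste0(sample(c("A","C","G","T"), 80, TRUE), collapse = "")
amplicon <- paste0(flank5, "TTC", "GCTGACGTATGCAATGCTAC", flank3)

site <- target_site(amplicon, spacer = "GCTGACGTATGCAATGCTAC", pam = "TTC")
print(site)
#> Cas12f1 target site on 'amplicon' (143 bp)
#>   spacer      : GCTGACGTATGCAATGCTAC (20 nt)
#>   PAM         : TTC (pattern TTC), positions 41-43 (+)
#>   cut centre  : after base 66 (23 bp from PAM)
#>   window      : positions 61-72 (12 bp)

ctl <- simulate_negative_control(site, sim_config(seed = 2, depth = 40000))
smp <- simulate_amplicon_reads(site, sim_config(seed = 3, depth = 2000,
                                                edit_fraction = 0.2))
cs  <- call_sample(smp$reads, site, tally_sample(ctl$reads, site),
                   sample_id = "treated_1")
summary(cs)
#> sample call set 'treated_1' (site amplicon)
#>   reads: 2000 total = 384 mutant + 1616 wild-type + 0 discarded + 0 unaligned
#>   indel frequency: 19.2% of aligned reads (mutant/wild-type ratio 0.2376)
#>   indel types: 205 observed in window, 200 retained at the 30x control filter
#>      key     kind position inserted count control_count retained
#>  D:65-71 deletion    66-71             11             0     TRUE
#>  D:62-66 deletion    63-66             10             0     TRUE
#>  ...
```

The sample was simulated with a true edit fraction of 0.20; the call set
recovers 19.2% mutant reads (the shortfall is the handful of 1-bp edits
that are statistically indistinguishable from sequencing-error background
and are correctly removed by the 30× filter). `position` is 1-based
closed; `D:65-71` is the 0-based half-open key of a 6-bp deletion
spanning the cut centre. `run_pipeline("config.yaml")` chains simulation,
calling, plant classification and off-target scanning behind one YAML
config, and `inst/cli/cas12fkit.R` exposes the same stages as shell
subcommands.

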