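# Example Cas12f1 site declaration (synthetic amplicon).
site:
  amplicon_fasta: example_amplicon.fasta
  amplicon_id: waxy_amplicon_synthetic
  spacer: GCTGACGTATGCAATGCTAC
  pam: TTC
  cut_offset: 23
  window_width: 12
simulate:
  depth: 2000
  edit_fraction: 0.2
call:
  multiplier: 30
  quality_threshold: 13
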