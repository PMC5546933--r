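loci:
- name: demo-locus
  amplicon: AACGGACGATGCGTGTATGGCTGTGAGACTAAGCTCTACTCGAAACATCTTTCGTGCCACGGGTGATGACTCTCTTGTCCAGGATATCGCATCCCCACACCACGAGGACCGTAGTTTCCTTGTTCCGAAATAACGACTCGCATACACAGCGGCTTTCGTTGAGGGCTTGATAAGGGTGGTCCACGTTGATAAAATCATAGCGA
  protospacer_start: 60
  strand: +
  guide_name: demo-guide
  guide: GGGTGATGACTCTCTTGTCC
groups:
- name: demo-group
  locus: demo-locus
  fasta: pool.fasta
thresholds:
  min_support: 1.0
  min_qual: 30.0
  flank: 100
  max_mm: 5
  seed_len: 10
  min_run: 8
  window:
  - 4
  - 8
seed: 101
outdir: ~
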