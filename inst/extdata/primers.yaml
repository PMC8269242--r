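# Primer definitions. Sequences are written 5'->3' as the primer anneals;
# coordinates are 1-based inclusive positions of the binding site on the
# E. coli K-12 MG1655 16S rRNA gene (reference name Ec16S). `targets`
# lists the organismal categories the primer is expected to bind and
# drives the taxonomic-overlap correction for pairs: 806RB and 785R have
# no 18S rRNA binding site, so pairs built on them report no Eukarya
# coverage.
primers:
  - name: 515Y
    sequence: GTGYCAGCMGCCGCGGTAA
    orientation: forward
    reference: Ec16S
    ref_start: 515
    targets: [Archaea, Bacteria, Cyanobacteria_plastid, Eukarya]
  - name: 806RB
    sequence: GGACTACNVGGGTWTCTAAT
    orientation: reverse
    reference: Ec16S
    ref_start: 787
    targets: [Archaea, Bacteria, Cyanobacteria_plastid]
  - name: 926R
    sequence: CCGYCAATTYMTTTRAGTTT
    orientation: reverse
    reference: Ec16S
    ref_start: 907
    targets: [Archaea, Bacteria, Cyanobacteria_plastid, Eukarya]
  - name: 785R
    sequence: GACTACHVGGGTATCTAATCC
    orientation: reverse
    reference: Ec16S
    ref_start: 785
    targets: [Archaea, Bacteria, Cyanobacteria_plastid]
pairs:
  - fwd: 515Y
    rev: 806RB
  - fwd: 515Y
    rev: 926R
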