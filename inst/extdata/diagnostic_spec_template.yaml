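# Template diagnostic spec for CPS functional classification.
#
# PLACEHOLDER POSITIONS: the five diagnostic residues of the glutamine
# amidotransferase domain (Cys-His-Glu catalytic triad plus the two
# glutamine-binding residues) are marked only graphically in published
# alignment figures; fill in the 1-based ungapped positions on your
# reference sequence from figure inspection or from the biochemical
# literature before production use. The window shown corresponds to the
# commonly figured residue range 278-397.
ref_id: A_alcalica_CPSIII
triad:
  Cys: 292
  His: 336
  Glu: 338
gln_binding:
- 310
- 365
gln_expected:
- S
- Q
window:
- 278
- 397
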