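# Domain partition for a myosin VI motor domain, as author residue-number
# ranges (resolved against the structure actually loaded).
#
# IMPORTANT: these ranges are an interpretation. Crystallographic papers on
# the pre-/post-powerstroke conformations do not print the exact subunit
# boundaries used for their analyses, so the big/small subunit split, the
# converter boundary and the nucleotide-motif windows below are editorial
# choices based on standard myosin domain annotations. Treat this file as a
# starting point and adjust it to the structures and numbering you use.
#
# Nucleotide-binding motifs (porcine myosin VI numbering):
#   P-loop    GESGAGKT   ~ 152-159
#   switch I  ~ 203-218
#   switch II DIYGFE     ~ 404-416
MH:
  ranges:
  - [1, 712]
converter:
  ranges:
  - [713, 788]
MH_big:
  ranges:
  - [1, 398]
MH_small:
  ranges:
  - [399, 712]
P_loop:
  ranges:
  - [152, 159]
switch_I:
  ranges:
  - [203, 218]
switch_II:
  ranges:
  - [404, 416]
# Filament beads, when present in the same coordinate set, are usually on
# their own chain; give the chain and range explicitly, e.g.
# actin:
#   chain: F
#   ranges:
#   - [1, 200]
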