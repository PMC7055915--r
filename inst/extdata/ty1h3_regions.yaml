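# Functional region annotation on the 5918-bp Ty1-H3 reference element,
# 1-based inclusive coordinates.  gag/pol/LTR intervals follow the
# reference feature layout; the p22 interval is the C-terminal half of gag
# rounded to the gag codon frame, and the helix / antisense intervals are
# synthetic placeholder defaults.  Every entry can be overridden by
# supplying a custom file to load_region_annotation().
element_length: 5918
LTR5: [1, 334]
gag: [294, 1616]
pol: [1578, 5561]
LTR3: [5585, 5918]
# p22 is encoded in the C-terminal half of gag; default start = gag codon 221
p22_region: [954, 1616]
# two alternative in-frame start codons for p22 (positions of the A of ATG)
p22_start_codons: [954, 1020]
# seven nucleotides required for +1 programmed frameshifting (gag/pol overlap)
frameshift_heptamer: [1571, 1577]
# nine predicted helical regions of Gag (synthetic placeholder intervals)
helix_regions:
  - [310, 360]
  - [400, 450]
  - [500, 550]
  - [610, 660]
  - [720, 770]
  - [830, 880]
  - [960, 1010]
  - [1100, 1150]
  - [1300, 1350]
# gag regions producing antisense RNAs (synthetic placeholder intervals)
antisense_regions:
  - [600, 1000]
  - [1200, 1400]
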