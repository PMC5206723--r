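# Consensus-frequency splice-site weight matrices (percent of each
# base observed at each position around mammalian splice sites;
# Shapiro-Senapathy-style consensus-value scoring). Editable: scores
# are affine-invariant in these weights, so any frequency-like scale
# works. Positions are transcription-oriented; "exonic" gives the
# number of window bases on the exon side of the splice point.
donor:
  site_type: donor
  exonic: 3          # window: exon -3..-1 | intron +1..+6 (CAG|GTAAGT)
  positions: [-3, -2, -1, 1, 2, 3, 4, 5, 6]
  weights:
    A: [33, 60,  8,   0,   0, 57, 71,  5, 16]
    C: [37, 13,  4,   0,   0,  2,  8,  6, 17]
    G: [18, 14, 81, 100,   0, 39, 12, 84, 19]
    T: [12, 13,  7,   0, 100,  2,  9,  5, 48]
acceptor:
  site_type: acceptor
  exonic: 1          # window: intron -13..-1 | exon +1 ((Py)nNCAG|G)
  positions: [-13, -12, -11, -10, -9, -8, -7, -6, -5, -4, -3, -2, -1, 1]
  weights:
    A: [ 9, 10,  8, 11, 10,  9, 10,  9,  7, 24,  3, 100,   0, 25]
    C: [31, 30, 32, 29, 31, 30, 28, 31, 31, 30, 65,   0,   0, 14]
    G: [11, 10,  9, 10,  9, 11, 10,  9,  6, 21,  1,   0, 100, 49]
    T: [49, 50, 51, 50, 50, 50, 52, 51, 56, 25, 31,   0,   0, 12]
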