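# Synthetic reference frame for cryptophyte alpha-subunit classification.
# Columns are 1-based positions in the reference (closed-form) sequence.
# The frame starts at the conserved AP of the AP-x(9-10)-C motif; the
# chromophore-binding Cys sits at column 12. An insertion anchored after
# open_insertion_column (i.e. immediately before the Cys column) marks the
# open form; an insertion of ~7 residues anchored inside s2_h1_gap_span
# (between beta-strand S2 and helix H1) marks the open-braced form.
chromophore_cys_column: 12
open_insertion_column: 11
s2_h1_gap_span: [23, 30]
motif_start_column: 1
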