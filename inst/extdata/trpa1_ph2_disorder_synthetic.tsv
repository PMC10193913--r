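# Synthetic stand-in disorder track for the TRPA1 PH2 region (residues
# 917-924).  The real per-residue predictor output is not redistributable
# here; this fixture only preserves the region's reported mean disorder
# (0.4).  Residue letters are X because the fragment sequence is not
# packaged.
residue_number	residue	pd
917	X	0.35
918	X	0.38
919	X	0.42
920	X	0.45
921	X	0.40
922	X	0.41
923	X	0.39
924	X	0.40
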