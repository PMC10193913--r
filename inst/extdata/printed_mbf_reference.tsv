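# Reference segment mean-flexibility (mBf) values reported in the
# ion-channel flexibility literature for segments undergoing non-canonical
# helical transitions.  Ranges are full-length residue numbers where the
# source states them, NA otherwise.  Used as calibration anchor targets
# and as comparison references; the underlying per-residue scale of the
# source is unpublished, so these values are reference points, not
# quantities this package claims to regenerate from scratch.
protein_id	segment_name	start	end	helix_class	mbf
TRPV1	S4b	546	558	three10	1.6
hERG	S5-PH	574	586	three10	2.08
TRPA1	PH2	917	924	pi	2.4
TRPV3	S4-S5L-central	573	579	pi	1.4
TRPV3	S4-S5L	NA	NA	pi	1.3
TRPV5	S3	NA	NA	pi	1.46
TRPV5	S4	NA	NA	pi	1.36
TRPV5	S6	NA	NA	pi	1.25
TRPM8	S4b	NA	NA	three10	1.79
TRPM4	S4b	NA	NA	three10	1.88
Kv1.2-2.1-chimera	S4b	NA	NA	three10	2.24
Shaker-E	S4b	NA	NA	three10	2.03
KCNQ1	S4b	NA	NA	three10	1.92
MloK1	S4	NA	NA	three10	1.74
spHCN	S4	NA	NA	three10	1.77
HCN1	S4	NA	NA	three10	1.8
NaChBac	S4	NA	NA	three10	1.54
Kv1.2-2.1-chimera	S6t	NA	NA	three10	1.7
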