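protein_id	segment_name	start	end	helix_class
toyA	S6pi	5	15	pi
toyA	S4	20	30	three10
toyB	P1	3	12	pi
toyB	L1	20	33	loop
toyC	S1	1	20	alpha
toyC	S4b	25	40	three10
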