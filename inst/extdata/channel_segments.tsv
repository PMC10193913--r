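protein_id	segment_name	start	end	helix_class
mTRPV3	S6-pi	663	673	pi
hTRPV6	S6-pi	564	574	pi
hTRPM4	S6-pi	1029	1039	pi
mTRPM8	S6-pi	965	975	pi
hTRPC3	S6-pi	729	739	pi
hTRPA1	S6-pi	946	956	pi
Shaker	S4b	371	381	three10
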