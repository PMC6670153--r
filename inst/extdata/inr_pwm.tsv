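# Initiator (INR) core promoter element, canonical consensus YYANWYY
# hand-curated frequency matrix v1; pyrimidine-rich element with the
# +1 (transcription start) adenine at motif offset 2 (0-based)
# center=2
A	C	G	T
0.08	0.46	0.09	0.37
0.09	0.41	0.09	0.41
0.85	0.05	0.05	0.05
0.25	0.25	0.25	0.25
0.46	0.09	0.09	0.36
0.09	0.42	0.13	0.36
0.09	0.41	0.09	0.41
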