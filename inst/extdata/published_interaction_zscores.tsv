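gene	gem_K	cyt_K	gem_L	cyt_L
VPS27	-8.1	-9.1	14.3	5.2
HSE1	-3.3	1.2	6.5	0.0
PMR1	-3.8	-9.8	3.6	10.1
CPR3	2.1	1.6	-4.1	-2.8
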