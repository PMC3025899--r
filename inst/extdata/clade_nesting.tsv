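clade	parent	level
1-1	2-1	1
1-2	2-1	1
1-3	2-2	1
1-4	2-3	1
1-5	2-3	1
1-6	2-4	1
1-7	2-4	1
1-8	2-5	1
2-1	3-1	2
2-2	3-1	2
2-3	3-2	2
2-4	3-2	2
2-5	3-2	2
3-1	total	3
3-2	total	3
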