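step	condition	yes	no
1	any_significant	2	CONCLUSION:INCONCLUSIVE
2	tip_dc_small_or_interior_dc_large	3	11
3	dn_reversed	5	4
4	small_dc_clades_allopatric	9	CONCLUSION:RGF_IBD
9	deep_branch_small_dc	CONCLUSION:PAST_FRAG	CONCLUSION:RGF_LDD
5	large_dn_clades_nonoverlapping	6	CONCLUSION:RGF_LDD
6	deep_branch_sig_dn	CONCLUSION:PAST_FRAG	CONCLUSION:LDC
11	tip_dn_small_or_interior_dn_large	12	CONCLUSION:INCONCLUSIVE
12	significant_clades_allopatric	13	CONCLUSION:CRE
13	deep_branch_sig_dn	CONCLUSION:PAST_FRAG	CONCLUSION:LDC
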