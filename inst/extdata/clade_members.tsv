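haplotype	clade
H34	1-1
H35	1-1
H36	1-1
H37	1-1
H01	1-2
H02	1-2
H38	1-2
H03	1-3
H04	1-3
H05	1-3
H06	1-3
H07	1-3
H08	1-3
H09	1-4
H10	1-4
H11	1-4
H12	1-4
H13	1-4
H14	1-5
H15	1-5
H16	1-5
H17	1-5
H18	1-5
H19	1-5
H30	1-6
H31	1-6
H32	1-6
H33	1-6
H24	1-7
H25	1-7
H26	1-7
H27	1-7
H28	1-7
H29	1-7
H20	1-8
H21	1-8
H22	1-8
H23	1-8
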