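SET	CHR	SNP	BP	A1	F_A	F_U	A2	P	OR	GENES
ligand_gated_ion_channel_signaling	4	rs1391174	46072596	T	0.4892	0.4586	C	1.764e-05	1.131	GABRG1
ligand_gated_ion_channel_signaling	5	rs9790873	45291514	C	0.1535	0.1335	T	5.621e-05	1.177	HCN1
ligand_gated_ion_channel_signaling	9	rs2259639	101317401	T	0.2751	0.2982	C	0.0003612	0.8928	GABBR2
ligand_gated_ion_channel_signaling	9	rs1930415	101238974	T	0.2218	0.2424	C	0.0007006	0.8908	GABBR2
ligand_gated_ion_channel_signaling	11	rs949054	120795888	C	0.2241	0.2053	T	0.001281	1.118	GRIK4
lymphocytes	19	rs16986092	55433696	T	0.1158	0.09473	C	1.093e-06	1.251	NCR1|NLRP7
lymphocytes	13	rs1933437	28624294	G	0.4183	0.3871	A	8.482e-06	1.138	FLT3
lymphocytes	3	rs2243123	159709651	C	0.2515	0.2759	T	0.0001167	0.8817	IL12A
lymphocytes	7	rs3801983	18683672	C	0.1928	0.2133	T	0.0003981	0.8808	HDAC9
lymphocytes	5	rs2230525	66478626	C	0.08431	0.07127	T	0.0005641	1.2	CD180
cell_adhesion_transsynaptic_signaling	20	rs1002762	58580885	G	0.2305	0.2028	A	2.031e-06	1.178	CDH26
cell_adhesion_transsynaptic_signaling	21	rs2826825	22762779	G	0.376	0.3487	A	6.698e-05	1.126	NCAM2
cell_adhesion_transsynaptic_signaling	11	rs7925725	131449365	C	0.3709	0.3979	A	0.0001099	0.8921	NTM
cell_adhesion_transsynaptic_signaling	11	rs12224080	131816849	G	0.09841	0.08353	A	0.0002519	1.198	NTM
cell_adhesion_transsynaptic_signaling	3	rs6773575	77060574	C	0.0964	0.1126	A	0.000256	0.8407	ROBO2
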