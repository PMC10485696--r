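snp	chrom_pos	effect_allele	eaf	beta_exposure	se_exposure	pval_exposure	beta_outcome	se_outcome	pval_outcome	n_exposure	n_outcome
rs10455872	6: 161010118	G	0.0810412	0.0133593	0.00150604	7.31E-19	-0.00682856	0.00376191	0.0694992	337159	83529
rs117733303	6: 160922870	G	0.0186833	0.0196617	0.00303468	9.25E-11	-0.00807061	0.00759619	0.288032	337159	83529
rs1831733	9: 22076071	C	0.475704	0.00723124	0.000826446	2.15E-18	-0.00302929	0.00206174	0.141758	337159	83529
rs2521501	15: 91437388	T	0.322313	0.00490502	0.00088581	3.07E-08	-0.00294589	0.00221074	0.182687	337159	83529
rs583104	1: 109821307	G	0.42184	-0.00486719	0.00084236	7.56E-09	-0.0028417	0.00210676	0.177388	337159	83529
rs73015016	19: 11191300	T	0.773202	0.00622211	0.00098108	2.27E-10	-0.00137204	0.00245182	0.575751	337159	83529
rs7412	19: 45412079	A	0.118872	-0.00726876	0.00126954	1.03E-08	0.000856574	0.00317097	0.78706	337159	83529
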