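# Published blind protein-peptide docking scores for the five high-affinity
# candidates from the rice storage-protein digests (score: HPEPDOCK-style,
# more negative = higher affinity; binding_energy: rescoring of the docked
# pose, kcal/mol; interactions: receptor residues of the reported
# hydrogen bonds).
peptide	score	binding_energy	interactions	fraction_reported
IVPQH	-170.40	-1.87	CYS285	glutelin
PIVF	-188.22	-2.18	SER289,CYS285	glutelin
IIQGR	-170.12	-2.07	ARG288	glutelin
QPY	-168.94	-5.61	CYS285,SER289,TYR473	prolamin
QSPVF	-175.73	-6.38	CYS285,GLY284	prolamin
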