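# Externally computed octanol/water partition coefficients (GB/SA-based
# iLOGP) for the five candidate peptides, consumed as input by the
# screening pipeline.
peptide	logp
IVPQH	2.25
PIVF	2.36
IIQGR	1.28
QPY	1.34
QSPVF	2.32
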