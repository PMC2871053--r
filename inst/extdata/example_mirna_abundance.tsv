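mirna	sequence	nuclear_rpm	cytoplasmic_rpm
miR-32	UAUUGCACAUUACUAAGUUGCAU	15.6	2.5
miR-148a	UCAGUGCACUACAGAACUUUGU	41.9	8.6
miR-29b	UAGCACCAUUUGAAAUCAGUGUU	355.3	78.2
miR-148b	UCAGUGCAUCACAGAACUUUGU	145.1	39
miR-1	UGGAAUGUAAAGAAGUAUGUAU	43.4	12.5
miR-1285	UCUGGGCAACAAAGUGAGACCU	19	5.9
miR-652	AAUGGCGCCACUAGGGUUGUG	10.7	3.7
miR-29c	UAGCACCAUUUGAAAUCGGUUA	222.7	78.4
miR-15b	UAGCAGCACAUCAUGGUUUACA	52.6	19.1
miR-135b	UAUGGCUUUUCAUUCCUAUGUGA	13.5	5.1
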