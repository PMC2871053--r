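trna	sequence	cytoplasmic_rpm	nuclear_rpm
tRNA-Ser (TGA)	GAAGCGGGUGCUCUUAUUU	39889.0	264.2
tRNA-Arg (ACG)	GUGUAAGCAGGGUCGUUUU	1176.6	196.0
tRNA-Ala (CGC)	AGGCGAUCACGUAGAUUUUGUUUA	853.0	203.3
tRNA-Thr (CGT)	AGGGUGUGCGUGUUUUUUU	349.3	144.7
tRNA-Phe (GAA)	GAGAGCGCUCGGUUUUU	316.9	23.7
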