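class	nuclear	cytoplasmic
total	5321867	4079549
box C/D snoRNA	174833	3132
ETS	40913	3266
box H/ACA snoRNA	2780	353
scaRNA	14027	5175
miRNA	4208498	2156495
ITS	3225	1879
mRNA	117038	74840
snRNA	13881	11140
SRP RNA	2919	3256
rRNA	237973	367524
hY RNA	8033	22629
tRNA	111904	476974
mitochondrial RNA	33690	311742
tRNA 3' trailer	6295	180657
genomic repeat	64527	117314
miscRNA	1119	1281
unknown	280215	341913
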