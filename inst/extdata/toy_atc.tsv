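code	parent	label	level
ATC	NA	ATC root	root
A	ATC	Alimentary tract and metabolism	level1
A01	A	Stomatological preparations	level2
A01A	A01	Stomatological preparations	level3
A01AB	A01A	Antiinfectives for local oral treatment	level4
B	ATC	Blood and blood forming organs	level1
B03	B	Antianemic preparations	level2
B03B	B03	Vitamin B12 and folic acid	level3
B03BA	B03B	Vitamin B12 (cyanocobalamin and analogues)	level4
B03BB	B03B	Folic acid and derivatives	level4
J	ATC	Antiinfectives for systemic use	level1
J01	J	Antibacterials for systemic use	level2
J01D	J01	Other beta-lactam antibacterials	level3
J01DD	J01D	Third-generation cephalosporins	level4
J01DD14	J01DD	Ceftibuten	level5
J01E	J01	Sulfonamides and trimethoprim	level3
J01EA	J01E	Trimethoprim and derivatives	level4
J01EA01	J01EA	Trimethoprim	level5
J07	J	Vaccines	level2
J07B	J07	Viral vaccines	level3
J07BC	J07B	Hepatitis vaccines	level4
J07BC20	J07BC	Hepatitis A and B combination vaccine	level5
N	ATC	Nervous system	level1
N02	N	Analgesics	level2
N02B	N02	Other analgesics and antipyretics	level3
N02BE	N02B	Anilides	level4
R	ATC	Respiratory system	level1
R05	R	Cough and cold preparations	level2
R05C	R05	Expectorants, excluding combinations with cough suppressants	level3
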