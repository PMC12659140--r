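code	parent	label	level
ICD10	NA	ICD-10 root	root
A00-B99	ICD10	Ch. I Certain infectious and parasitic diseases	chapter
A00-A09	A00-B99	Intestinal infectious diseases	block
A08	A00-A09	Viral and other specified intestinal infections	category
A09	A00-A09	Diarrhoea and gastroenteritis of presumed infectious origin	category
B25-B34	A00-B99	Other viral diseases	block
B25	B25-B34	Cytomegaloviral disease	category
B34	B25-B34	Viral infection of unspecified site	category
B342	B34	Coronavirus infection, unspecified site	subcategory
B349	B34	Viral infection, unspecified	subcategory
D50-D89	ICD10	Ch. III Diseases of the blood and blood-forming organs	chapter
D55-D59	D50-D89	Haemolytic anaemias	block
D55	D55-D59	Anaemia due to enzyme disorders	category
D56	D55-D59	Thalassaemia	category
G00-G99	ICD10	Ch. VI Diseases of the nervous system	chapter
G00-G09	G00-G99	Inflammatory diseases of the central nervous system	block
G00	G00-G09	Bacterial meningitis, not elsewhere classified	category
G04	G00-G09	Encephalitis, myelitis and encephalomyelitis	category
H00-H59	ICD10	Ch. VII Diseases of the eye and adnexa	chapter
H10-H13	H00-H59	Disorders of conjunctiva	block
H10	H10-H13	Conjunctivitis	category
H60-H95	ICD10	Ch. VIII Diseases of the ear and mastoid process	chapter
H65-H75	H60-H95	Diseases of middle ear and mastoid	block
H65	H65-H75	Nonsuppurative otitis media	category
H66	H65-H75	Suppurative and unspecified otitis media	category
H70	H65-H75	Mastoiditis and related conditions	category
J00-J99	ICD10	Ch. X Diseases of the respiratory system	chapter
J00-J06	J00-J99	Acute upper respiratory infections	block
J03	J00-J06	Acute tonsillitis	category
J06	J00-J06	Acute upper respiratory infections of multiple sites	category
M00-M99	ICD10	Ch. XIII Diseases of the musculoskeletal system	chapter
M40-M54	M00-M99	Dorsopathies	block
M40	M40-M54	Kyphosis and lordosis	category
M43	M40-M54	Other deforming dorsopathies	category
P00-P96	ICD10	Ch. XVI Certain conditions originating in the perinatal period	chapter
P05-P08	P00-P96	Disorders related to length of gestation and fetal growth	block
P07	P05-P08	Disorders related to short gestation and low birth weight	category
Q00-Q99	ICD10	Ch. XVII Congenital malformations, deformations and chromosomal abnormalities	chapter
Q20-Q28	Q00-Q99	Congenital malformations of the circulatory system	block
Q21	Q20-Q28	Congenital malformations of cardiac septa	category
R00-R99	ICD10	Ch. XVIII Symptoms, signs and abnormal findings	chapter
R50-R69	R00-R99	General symptoms and signs	block
R62	R50-R69	Lack of expected normal physiological development	category
R620	R62	Delayed milestone	subcategory
S00-T98	ICD10	Ch. XIX Injury, poisoning and certain other consequences of external causes	chapter
S00-S09	S00-T98	Injuries to the head	block
S06	S00-S09	Intracranial injury	category
Z00-Z99	ICD10	Ch. XXI Factors influencing health status and contact with health services	chapter
Z00-Z13	Z00-Z99	Persons encountering health services for examination	block
Z00	Z00-Z13	General examination of persons without complaint	category
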