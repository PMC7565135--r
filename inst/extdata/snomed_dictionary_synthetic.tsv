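code	description
M-00100	Normal tissue (finding)
M-09350	Morphologic description only (finding)
M-36300	Edema (morphologic abnormality)
M-40000	Inflammation (morphologic abnormality)
M-41000	Acute inflammation (morphologic abnormality)
M-43000	Chronic inflammation (morphologic abnormality)
M-44000	Granulomatous inflammation (morphologic abnormality)
M-58000	Atrophy (morphologic abnormality)
M-69700	Atypia (morphologic abnormality)
M-71000	Hypertrophy (morphologic abnormality)
M-72000	Hyperplasia (morphologic abnormality)
M-72400	Adenosis (morphologic abnormality)
M-72440	Glandular and muscular hyperplasia (morphologic abnormality)
M-72450	Adenofibromyomatous hyperplasia (morphologic abnormality)
M-74000	Dysplasia (morphologic abnormality)
M-74008	High grade intraepithelial neoplasia (morphologic abnormality)
M-80001	Neoplasm, uncertain whether benign or malignant (morphologic abnormality)
M-80003	Malignant neoplasm, primary (morphologic abnormality)
M-80103	Carcinoma (morphologic abnormality)
M-81403	Adenocarcinoma, no subtype (morphologic abnormality)
T-28000	Prostatic structure
T-74000	Seminal vesicle structure
T-92000	Prostatic structure
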