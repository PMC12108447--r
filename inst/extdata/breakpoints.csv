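drug,organism,breakpoint_mg_L,source_tag
ampicillin,Escherichia coli,8,CLSI-style bundled defaults (synthetic fixture)
aztreonam,Pseudomonas aeruginosa,8,CLSI-style bundled defaults (synthetic fixture)
aztreonam,Escherichia coli,4,CLSI-style bundled defaults (synthetic fixture)
aztreonam,Klebsiella pneumoniae,4,CLSI-style bundled defaults (synthetic fixture)
cefazolin,Escherichia coli,2,CLSI-style bundled defaults (synthetic fixture)
cefazolin,Klebsiella pneumoniae,2,CLSI-style bundled defaults (synthetic fixture)
cefazolin,Staphylococcus aureus,2,CLSI-style bundled defaults (synthetic fixture)
cefepime,Pseudomonas aeruginosa,8,CLSI-style bundled defaults (synthetic fixture)
cefepime,Escherichia coli,2,CLSI-style bundled defaults (synthetic fixture)
cefepime,Klebsiella pneumoniae,2,CLSI-style bundled defaults (synthetic fixture)
ceftriaxone,Escherichia coli,1,CLSI-style bundled defaults (synthetic fixture)
ceftriaxone,Klebsiella pneumoniae,1,CLSI-style bundled defaults (synthetic fixture)
meropenem,Pseudomonas aeruginosa,2,CLSI-style bundled defaults (synthetic fixture)
meropenem,Escherichia coli,1,CLSI-style bundled defaults (synthetic fixture)
meropenem,Klebsiella pneumoniae,1,CLSI-style bundled defaults (synthetic fixture)
oxacillin,Staphylococcus aureus,2,CLSI-style bundled defaults (synthetic fixture)
piperacillin,Pseudomonas aeruginosa,16,CLSI-style bundled defaults (synthetic fixture)
piperacillin,Escherichia coli,8,CLSI-style bundled defaults (synthetic fixture)
piperacillin,Klebsiella pneumoniae,8,CLSI-style bundled defaults (synthetic fixture)
ampicillin,Enterococcus faecalis,8,CLSI-style bundled defaults (synthetic fixture)
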