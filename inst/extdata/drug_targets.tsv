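gene	drug
ALK	Crizotinib
ALK	Alectinib
ALK	Ceritinib
ALK	Brigatinib
BRAF	Vemurafenib
BRAF	Dabrafenib
BRAF	Cobimetinib
BRAF	Trametinib
DNMT3A	Azacitidine
DNMT3A	Decitabine
EGFR	Erlotinib
EGFR	Afatinib
EGFR	Gefitinib
ERBB2	Neratinib
ERBB2	Lapatinib
JAK2	Ruxolitinib
KIT	Imatinib
KIT	Dasatinib
KIT	Regorafenib
MET	Crizotinib
MET	Cabozantinib
PDGFRA	Axitinib
PDGFRA	Regorafenib
PDGFRB	Axitinib
PDGFRB	Regorafenib
PIK3CA	Idelalisib
PIK3CA	Everolimus
RET	Cabozantinib
RET	Vandetanib
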