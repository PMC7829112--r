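asv_id	lineage
asv1	Bacteria;Firmicutes;Clostridia
asv2	Bacteria;Firmicutes;Bacilli
asv3	Bacteria;Bacteroidetes;Bacteroidia
asv4	Bacteria;Proteobacteria;Gammaproteobacteria
asv5	Bacteria;Verrucomicrobia;Verrucomicrobiae
tox1	Bacteria;Proteobacteria;Alphaproteobacteria;Rickettsiales;Mitochondria
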