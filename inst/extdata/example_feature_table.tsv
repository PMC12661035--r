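# minimal demo feature table: id, semicolon lineage, one column per sample
feature_id	lineage	inoc1	printA	printB
asv001	Bacteria;Bacillota;Bacilli;Lactobacillales;Streptococcaceae;Streptococcus;Streptococcus oralis	410	380	120
asv002	Bacteria;Bacillota;Bacilli;Lactobacillales;Streptococcaceae;Streptococcus;Streptococcus mutans	120	85	40
asv003	Bacteria;Actinomycetota;Actinomycetia;Actinomycetales;Actinomycetaceae;Actinomyces	95	0	12
asv004	Bacteria;Fusobacteriota;Fusobacteriia;Fusobacteriales;Fusobacteriaceae;Fusobacterium;Fusobacterium nucleatum	60	22	0
asv005	Bacteria;Bacteroidota;Bacteroidia	15	0	3
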