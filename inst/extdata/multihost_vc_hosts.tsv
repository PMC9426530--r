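vc_id	n_genomes	genus	family	order	class	phylum
vOTU_1233	7	Salmonella	Enterobacteriaceae	Enterobacterales	Gammaproteobacteria	Proteobacteria
vOTU_1233	2	Klebsiella	Enterobacteriaceae	Enterobacterales	Gammaproteobacteria	Proteobacteria
vOTU_94	3	Ralstonia	Burkholderiaceae	Burkholderiales	Betaproteobacteria	Proteobacteria
vOTU_94	1	Streptomyces	Streptomycetaceae	Streptomycetales	Actinomycetia	Actinobacteria
vOTU_1254	2	Odoribacter	Odoribacteraceae	Bacteroidales	Bacteroidia	Bacteroidetes
vOTU_1254	1	Parabacteroides	Tannerellaceae	Bacteroidales	Bacteroidia	Bacteroidetes
vOTU_1158	1	Mycobacteroides	Mycobacteriaceae	Corynebacteriales	Actinomycetia	Actinobacteria
vOTU_1158	1	Mycolicibacterium	Mycobacteriaceae	Corynebacteriales	Actinomycetia	Actinobacteria
vOTU_1237	1	Mycobacteroides	Mycobacteriaceae	Corynebacteriales	Actinomycetia	Actinobacteria
vOTU_1237	1	Mycolicibacterium	Mycobacteriaceae	Corynebacteriales	Actinomycetia	Actinobacteria
vOTU_51	1	Mycobacteroides	Mycobacteriaceae	Corynebacteriales	Actinomycetia	Actinobacteria
vOTU_51	1	Mycolicibacterium	Mycobacteriaceae	Corynebacteriales	Actinomycetia	Actinobacteria
vOTU_831	1	Mycobacteroides	Mycobacteriaceae	Corynebacteriales	Actinomycetia	Actinobacteria
vOTU_831	1	Mycolicibacterium	Mycobacteriaceae	Corynebacteriales	Actinomycetia	Actinobacteria
vOTU_1201	1	Mixta	Erwiniaceae	Enterobacterales	Gammaproteobacteria	Proteobacteria
vOTU_1201	1	Salmonella	Enterobacteriaceae	Enterobacterales	Gammaproteobacteria	Proteobacteria
vOTU_1442	1	Sodalis	Pectobacteriaceae	Enterobacterales	Gammaproteobacteria	Proteobacteria
vOTU_1442	1	Citrobacter	Enterobacteriaceae	Enterobacterales	Gammaproteobacteria	Proteobacteria
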