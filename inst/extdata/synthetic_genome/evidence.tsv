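gene_id	signal_peptide	localization	domains
sim_0001	TRUE	membrane	Cytochrome_c;S-layer
sim_0002	FALSE	extracellular	Cytochrome_c;S-layer
sim_0003	FALSE	membrane	Cytochrome_c
sim_0004	FALSE	membrane	Cytochrome_c
sim_0005	FALSE	membrane	Cytochrome_c
sim_0006	FALSE	membrane	Cytochrome_c
sim_0007	FALSE	cytoplasmic	
sim_0008	FALSE	cytoplasmic	
sim_0009	FALSE	cytoplasmic	
sim_0010	FALSE	cytoplasmic	
sim_0011	FALSE	cytoplasmic	
sim_0012	FALSE	cytoplasmic	
sim_0013	FALSE	cytoplasmic	
sim_0014	FALSE	cytoplasmic	
sim_0015	FALSE	cytoplasmic	
sim_0016	FALSE	cytoplasmic	
sim_0017	FALSE	cytoplasmic	
sim_0018	FALSE	cytoplasmic	
sim_0019	FALSE	cytoplasmic	
sim_0020	FALSE	cytoplasmic	
sim_0021	FALSE	cytoplasmic	
sim_0022	FALSE	cytoplasmic	
sim_0023	FALSE	cytoplasmic	
sim_0024	FALSE	cytoplasmic	
sim_0025	FALSE	cytoplasmic	
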