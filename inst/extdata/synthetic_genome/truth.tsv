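gene_id	is_mhc	heme_count	extracellular	slayer	cluster_context
sim_0001	TRUE	3	TRUE	TRUE	oxidoreductase-cluster
sim_0002	TRUE	4	TRUE	TRUE	oxidoreductase-cluster
sim_0003	TRUE	6	FALSE	FALSE	oxidoreductase-cluster
sim_0004	TRUE	8	FALSE	FALSE	standalone
sim_0005	TRUE	12	FALSE	FALSE	standalone
sim_0006	TRUE	22	FALSE	FALSE	standalone
sim_0007	FALSE	0	FALSE	FALSE	NA
sim_0008	FALSE	0	FALSE	FALSE	NA
sim_0009	FALSE	0	FALSE	FALSE	NA
sim_0010	FALSE	0	FALSE	FALSE	NA
sim_0011	FALSE	0	FALSE	FALSE	NA
sim_0012	FALSE	0	FALSE	FALSE	NA
sim_0013	FALSE	0	FALSE	FALSE	NA
sim_0014	FALSE	0	FALSE	FALSE	NA
sim_0015	FALSE	0	FALSE	FALSE	NA
sim_0016	FALSE	0	FALSE	FALSE	NA
sim_0017	FALSE	0	FALSE	FALSE	NA
sim_0018	FALSE	0	FALSE	FALSE	NA
sim_0019	FALSE	0	FALSE	FALSE	NA
sim_0020	FALSE	0	FALSE	FALSE	NA
sim_0021	FALSE	0	FALSE	FALSE	NA
sim_0022	FALSE	0	FALSE	FALSE	NA
sim_0023	FALSE	0	FALSE	FALSE	NA
sim_0024	FALSE	0	FALSE	FALSE	NA
sim_0025	FALSE	0	FALSE	FALSE	NA
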