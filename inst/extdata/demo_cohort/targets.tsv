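mirna_id	gene_id	evidence
mir001	GENE0001	high
mir011	GENE0002	high
mir026	GENE0003	high
mir027	GENE0004	high
mir020	GENE0005	high
mir011	GENE0006	high
mir019	GENE0007	high
mir009	GENE0008	high
mir030	GENE0009	high
mir023	GENE0010	high
mir008	GENE0011	high
mir001	GENE0012	high
mir021	GENE0013	high
mir013	GENE0014	high
mir017	GENE0015	high
mir027	GENE0016	high
mir009	GENE0017	high
mir011	GENE0018	high
mir022	GENE0019	high
mir001	GENE0020	high
mir008	GENE0021	high
mir030	GENE0022	high
mir011	GENE0023	high
mir008	GENE0024	high
mir008	GENE0025	high
mir026	GENE0026	high
mir022	GENE0027	high
mir015	GENE0028	high
mir025	GENE0029	high
mir013	GENE0030	high
mir005	GENE0031	high
mir021	GENE0032	high
mir009	GENE0033	high
mir008	GENE0034	high
mir010	GENE0035	high
mir009	GENE0036	high
mir011	GENE0037	high
mir027	GENE0038	high
mir021	GENE0039	high
mir012	GENE0040	high
mir004	GENE0041	high
mir026	GENE0042	high
mir030	GENE0043	high
mir017	GENE0044	high
mir030	GENE0045	high
mir023	GENE0046	high
mir005	GENE0047	high
mir015	GENE0048	high
mir012	GENE0049	high
mir023	GENE0050	high
mir016	GENE0051	high
mir018	GENE0052	high
mir001	GENE0053	high
mir025	GENE0054	high
mir009	GENE0055	high
mir019	GENE0056	high
mir026	GENE0057	high
mir009	GENE0058	high
mir026	GENE0059	high
mir021	GENE0060	high
mir025	GENE0043	high
mir030	GENE0061	high
mir005	GENE0070	high
mir004	GENE0067	high
mir001	GENE0039	high
mir009	GENE0062	high
mir026	GENE0058	high
mir005	GENE0062	high
mir020	GENE0057	high
mir002	GENE0006	high
mir029	GENE0004	high
mir025	GENE0038	high
mir011	GENE0004	high
mir026	GENE0004	high
mir016	GENE0070	high
mir015	GENE0068	high
mir029	GENE0066	high
mir003	GENE0056	high
mir018	GENE0031	high
mir005	GENE0020	high
mir014	GENE0040	high
mir029	GENE0029	high
mir014	GENE0029	high
mir011	GENE0049	high
mir014	GENE0005	high
mir018	GENE0033	high
mir009	GENE0001	high
mir030	GENE0075	high
mir008	GENE0030	high
mir010	GENE0061	high
mir004	GENE0018	high
mir017	GENE0067	high
mir012	GENE0003	high
mir002	GENE0050	high
mir012	GENE0033	high
mir018	GENE0050	high
mir002	GENE0025	high
mir005	GENE0008	high
mir012	GENE0020	high
mir026	GENE0062	high
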