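PLANTED_NEGATIVE	na	GENE0031	GENE0032	GENE0033	GENE0034	GENE0035	GENE0036	GENE0037	GENE0038	GENE0039	GENE0040	GENE0041	GENE0042	GENE0043	GENE0044	GENE0045	GENE0046	GENE0047	GENE0048	GENE0049	GENE0050	GENE0051	GENE0052	GENE0053	GENE0054	GENE0055	GENE0056	GENE0057	GENE0058	GENE0059	GENE0060
PLANTED_POSITIVE	na	GENE0001	GENE0002	GENE0003	GENE0004	GENE0005	GENE0006	GENE0007	GENE0008	GENE0009	GENE0010	GENE0011	GENE0012	GENE0013	GENE0014	GENE0015	GENE0016	GENE0017	GENE0018	GENE0019	GENE0020	GENE0021	GENE0022	GENE0023	GENE0024	GENE0025	GENE0026	GENE0027	GENE0028	GENE0029	GENE0030
RANDOM_SET_A	na	GENE0002	GENE0005	GENE0010	GENE0012	GENE0014	GENE0015	GENE0017	GENE0018	GENE0024	GENE0028	GENE0032	GENE0037	GENE0038	GENE0039	GENE0048	GENE0051	GENE0052	GENE0053	GENE0054	GENE0057	GENE0058	GENE0074	GENE0078	GENE0079	GENE0080
RANDOM_SET_B	na	GENE0004	GENE0005	GENE0008	GENE0010	GENE0011	GENE0014	GENE0015	GENE0017	GENE0018	GENE0020	GENE0021	GENE0025	GENE0026	GENE0027	GENE0028	GENE0029	GENE0030	GENE0033	GENE0035	GENE0036	GENE0039	GENE0040	GENE0041	GENE0045	GENE0048	GENE0049	GENE0050	GENE0054	GENE0055	GENE0056	GENE0058	GENE0059	GENE0062	GENE0063	GENE0064	GENE0065	GENE0068	GENE0078	GENE0079	GENE0080
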