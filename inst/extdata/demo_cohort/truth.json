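{"pattern":["Down-Up","NoChange-NoChange","NoChange-NoChange","NoChange-Up","NoChange-NoChange","NoChange-Down","Down-Up","Down-Up","NoChange-NoChange","NoChange-NoChange","NoChange-Up","NoChange-NoChange","NoChange-Up","NoChange-NoChange","Up-Down","NoChange-Up","Up-NoChange","NoChange-NoChange","Down-NoChange","Down-Up","Down-Down","NoChange-NoChange","Up-Up","NoChange-Up","Down-NoChange","Down-NoChange","Up-Up","NoChange-NoChange","Down-Down","NoChange-NoChange"],"log2fc_t1_t2":[-1.42522930225823,0,0,0,0,0,-1.18728973241057,-4.79822486376623,0,0,0,0,0,0,1.11789996961132,0,1.66844037890434,0,-1.04976180003257,-1.5132508956478,-3.66491160842357,0,1.6156837028265,0,-4.57098246170441,-1.41293164230417,2.64816394394264,0,-2.26815180551726,0],"log2fc_t2_term":[1.66019978340715,0,0,2.64904979523271,0,-3.1082507447293,2.2591423798725,1.19469391997904,0,0,2.52140769300982,0,2.49887428723276,0,-1.81427494684234,1.6618646687828,0,0,0,2.71996928216889,-2.39740434787236,0,2.30795073632151,1.57382321057841,0,0,2.56015114797279,0,-1.39021504208678,0],"pe_shift":[0,0,0,1.12019293219782,-1.34424340701662,0,0,0,0,0,0,0,0,0,0,0,0,0,1.01476964117028,0,0,0.847772515332326,0,0,0,-1.31594440024346,0,0,0,0],"eqtl":[{"snv_id":"rs000001","mirna_id":"mir015","beta":0.7,"maf":0.3},{"snv_id":"rs000002","mirna_id":"mir024","beta":0.7,"maf":0.3},{"snv_id":"rs000003","mirna_id":"mir007","beta":0.7,"maf":0.3},{"snv_id":"rs000004","mirna_id":"mir006","beta":0.7,"maf":0.3},{"snv_id":"rs000005","mirna_id":"mir013","beta":0.7,"maf":0.3}],"correlation":[{"gene_id":"GENE0001","mirna_id":"mir001","direction":"positive","strength":0.8},{"gene_id":"GENE0002","mirna_id":"mir011","direction":"positive","strength":0.8},{"gene_id":"GENE0003","mirna_id":"mir026","direction":"positive","strength":0.8},{"gene_id":"GENE0004","mirna_id":"mir027","direction":"positive","strength":0.8},{"gene_id":"GENE0005","mirna_id":"mir020","direction":"positive","strength":0.8},{"gene_id":"GENE0006","mirna_id":"mir011","direction":"positive","strength":0.8},{"gene_id":"GENE0007","mirna_id":"mir019","direction":"positive","strength":0.8},{"gene_id":"GENE0008","mirna_id":"mir009","direction":"positive","strength":0.8},{"gene_id":"GENE0009","mirna_id":"mir030","direction":"positive","strength":0.8},{"gene_id":"GENE0010","mirna_id":"mir023","direction":"positive","strength":0.8},{"gene_id":"GENE0011","mirna_id":"mir008","direction":"positive","strength":0.8},{"gene_id":"GENE0012","mirna_id":"mir001","direction":"positive","strength":0.8},{"gene_id":"GENE0013","mirna_id":"mir021","direction":"positive","strength":0.8},{"gene_id":"GENE0014","mirna_id":"mir013","direction":"positive","strength":0.8},{"gene_id":"GENE0015","mirna_id":"mir017","direction":"positive","strength":0.8},{"gene_id":"GENE0016","mirna_id":"mir027","direction":"positive","strength":0.8},{"gene_id":"GENE0017","mirna_id":"mir009","direction":"positive","strength":0.8},{"gene_id":"GENE0018","mirna_id":"mir011","direction":"positive","strength":0.8},{"gene_id":"GENE0019","mirna_id":"mir022","direction":"positive","strength":0.8},{"gene_id":"GENE0020","mirna_id":"mir001","direction":"positive","strength":0.8},{"gene_id":"GENE0021","mirna_id":"mir008","direction":"positive","strength":0.8},{"gene_id":"GENE0022","mirna_id":"mir030","direction":"positive","strength":0.8},{"gene_id":"GENE0023","mirna_id":"mir011","direction":"positive","strength":0.8},{"gene_id":"GENE0024","mirna_id":"mir008","direction":"positive","strength":0.8},{"gene_id":"GENE0025","mirna_id":"mir008","direction":"positive","strength":0.8},{"gene_id":"GENE0026","mirna_id":"mir026","direction":"positive","strength":0.8},{"gene_id":"GENE0027","mirna_id":"mir022","direction":"positive","strength":0.8},{"gene_id":"GENE0028","mirna_id":"mir015","direction":"positive","strength":0.8},{"gene_id":"GENE0029","mirna_id":"mir025","direction":"positive","strength":0.8},{"gene_id":"GENE0030","mirna_id":"mir013","direction":"positive","strength":0.8},{"gene_id":"GENE0031","mirna_id":"mir005","direction":"negative","strength":0.8},{"gene_id":"GENE0032","mirna_id":"mir021","direction":"negative","strength":0.8},{"gene_id":"GENE0033","mirna_id":"mir009","direction":"negative","strength":0.8},{"gene_id":"GENE0034","mirna_id":"mir008","direction":"negative","strength":0.8},{"gene_id":"GENE0035","mirna_id":"mir010","direction":"negative","strength":0.8},{"gene_id":"GENE0036","mirna_id":"mir009","direction":"negative","strength":0.8},{"gene_id":"GENE0037","mirna_id":"mir011","direction":"negative","strength":0.8},{"gene_id":"GENE0038","mirna_id":"mir027","direction":"negative","strength":0.8},{"gene_id":"GENE0039","mirna_id":"mir021","direction":"negative","strength":0.8},{"gene_id":"GENE0040","mirna_id":"mir012","direction":"negative","strength":0.8},{"gene_id":"GENE0041","mirna_id":"mir004","direction":"negative","strength":0.8},{"gene_id":"GENE0042","mirna_id":"mir026","direction":"negative","strength":0.8},{"gene_id":"GENE0043","mirna_id":"mir030","direction":"negative","strength":0.8},{"gene_id":"GENE0044","mirna_id":"mir017","direction":"negative","strength":0.8},{"gene_id":"GENE0045","mirna_id":"mir030","direction":"negative","strength":0.8},{"gene_id":"GENE0046","mirna_id":"mir023","direction":"negative","strength":0.8},{"gene_id":"GENE0047","mirna_id":"mir005","direction":"negative","strength":0.8},{"gene_id":"GENE0048","mirna_id":"mir015","direction":"negative","strength":0.8},{"gene_id":"GENE0049","mirna_id":"mir012","direction":"negative","strength":0.8},{"gene_id":"GENE0050","mirna_id":"mir023","direction":"negative","strength":0.8},{"gene_id":"GENE0051","mirna_id":"mir016","direction":"negative","strength":0.8},{"gene_id":"GENE0052","mirna_id":"mir018","direction":"negative","strength":0.8},{"gene_id":"GENE0053","mirna_id":"mir001","direction":"negative","strength":0.8},{"gene_id":"GENE0054","mirna_id":"mir025","direction":"negative","strength":0.8},{"gene_id":"GENE0055","mirna_id":"mir009","direction":"negative","strength":0.8},{"gene_id":"GENE0056","mirna_id":"mir019","direction":"negative","strength":0.8},{"gene_id":"GENE0057","mirna_id":"mir026","direction":"negative","strength":0.8},{"gene_id":"GENE0058","mirna_id":"mir009","direction":"negative","strength":0.8},{"gene_id":"GENE0059","mirna_id":"mir026","direction":"negative","strength":0.8},{"gene_id":"GENE0060","mirna_id":"mir021","direction":"negative","strength":0.8}],"dispersion":0.05,"library_sizes":[1150625.40788203,1076844.70722452,1066474.68646988,1178108.66059735,1089945.73270902,1036904.79239449,808423.364162445,1155741.9070974,924259.680416435,1044444.8386319,940451.722219586,984054.985456169,1079270.80113441,807198.892813176,1196801.79888383,902776.955999434,972727.120388299,1027101.62000731,922014.938201755,810867.728572339,908674.022834748,1165060.17008796,940863.564703614,828453.256376088,998268.129024655,1108281.24536201,986290.487181395,838840.271439403,835655.440017581,962983.658816665,1148886.45857573,928530.289512128,1022457.10380375,1147202.40365714,843631.001375616,950974.247511476,1146844.31105852,1004708.67268741,1040362.91949451,1091483.5867472,1172156.22123331,841865.770705044,988429.716508836,834330.822061747,1006166.46436974,1008913.53283077,956737.144757062,1106361.0823825,1131700.13865456,1120347.76229411,838686.577416956,807598.68491441]}
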