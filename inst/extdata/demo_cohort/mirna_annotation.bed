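chr19	53700000	53700080	mir001	.	+	C19MC
chr19	53712000	53712080	mir002	.	-	C19MC
chr19	53724000	53724080	mir003	.	+	C19MC
chr19	53736000	53736080	mir004	.	-	C19MC
chr19	53748000	53748080	mir005	.	+	C19MC
chr19	53760000	53760080	mir006	.	-	C19MC
chr19	53772000	53772080	mir007	.	+	C19MC
chr19	53784000	53784080	mir008	.	-	C19MC
chr14	101000000	101000080	mir009	.	+	C14MC
chr14	101030000	101030080	mir010	.	-	C14MC
chr14	101060000	101060080	mir011	.	+	C14MC
chr14	101090000	101090080	mir012	.	-	C14MC
chr14	101120000	101120080	mir013	.	+	C14MC
chr14	101150000	101150080	mir014	.	-	C14MC
chr14	101180000	101180080	mir015	.	+	C14MC
chr19	58000000	58000080	mir016	.	-	miR371_373
chr19	58000400	58000480	mir017	.	+	miR371_373
chr1	1000000	1000080	mir018	.	-	other
chr2	1500000	1500080	mir019	.	+	other
chr3	2000000	2000080	mir020	.	-	other
chr4	2500000	2500080	mir021	.	+	other
chr5	3000000	3000080	mir022	.	-	other
chr6	3500000	3500080	mir023	.	+	other
chr7	4000000	4000080	mir024	.	-	other
chr8	4500000	4500080	mir025	.	+	other
chr9	5000000	5000080	mir026	.	-	other
chr10	5500000	5500080	mir027	.	+	other
chr11	6000000	6000080	mir028	.	-	other
chr12	6500000	6500080	mir029	.	+	other
chr1	7000000	7000080	mir030	.	-	other
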