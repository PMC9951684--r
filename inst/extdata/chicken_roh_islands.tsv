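chrom	n_snps	start_bp	end_bp	n_genes	n_qtl
1	469	73276840	75884166	18	55
2	671	51100728	54046793	13	30
5	400	1912343	3909043	18	16
8	638	8946537	11679072	11	54
11	343	2365463	3771468	20	55
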