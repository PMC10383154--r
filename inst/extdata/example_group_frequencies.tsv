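variant_id	rsid	group	allele	freq	n_called
chr7:99767460:G:A	rs4646437	Black	A	0.725	NA
chr7:99767460:G:A	rs4646437	White	A	0.105	NA
chr16:31096368:C:T	rs9923231	Asian	T	0.674	NA
chr16:31096368:C:T	rs9923231	White	T	0.338	NA
chr1:11796321:G:A	rs1801133	Black	A	0.104	NA
chr1:11796321:G:A	rs1801133	White	A	0.348	NA
chr8:42298528:A:G	rs9694958	Black	A	0.333	NA
chr8:42298528:A:G	rs9694958	White	A	0.920	NA
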