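#readscreen_report	n_reads=9
#params	k=21	read_length=500	error_rate=0.01	target_matches=10	seed=42
#n_classified	9
#n_unclassified	0
#n_tied	0
#accuracy	1.000000
#unclassified_fraction	0.000000
#tie_fraction	0.000000
#per_genome	genome01	3	1.000000
#per_genome	genome02	3	1.000000
#per_genome	genome03	3	1.000000
read_id	predicted	score	n_shared	tied_with	status
genome01_read0001	genome01	12	12		classified
genome01_read0002	genome01	14	14		classified
genome01_read0003	genome01	12	12		classified
genome02_read0001	genome02	8	8		classified
genome02_read0002	genome02	8	8		classified
genome02_read0003	genome02	11	11		classified
genome03_read0001	genome03	13	13		classified
genome03_read0002	genome03	13	13		classified
genome03_read0003	genome03	8	8		classified
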