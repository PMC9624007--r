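read_id	genome_id	start	strand	n_errors
genome01_read0001	genome01	3369	-	4
genome01_read0002	genome01	1490	+	3
genome01_read0003	genome01	3486	-	2
genome02_read0001	genome02	405	+	7
genome02_read0002	genome02	2620	+	4
genome02_read0003	genome02	475	-	5
genome03_read0001	genome03	541	-	5
genome03_read0002	genome03	40	-	1
genome03_read0003	genome03	2555	+	10
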