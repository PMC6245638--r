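taxon_index	taxon_name
0	cellular organisms
1	Eukaryota
2	Opisthokonta
3	Metazoa
4	Bilateria
5	Deuterostomia
6	Chordata
7	Osteichthyes
8	Sarcopterygii
9	Tetrapoda
10	Amniota
11	Mammalia
12	Eutheria
13	Primates
14	Homo
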