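month	song_year	songs	inis
7	1	NA	NA
8	1	NA	NA
9	1	NA	NA
10	1	NA	NA
11	1	NA	NA
12	1	NA	NA
1	1	14	1681
2	1	12	804
3	1	9	480
4	1	4	182
5	1	0	0
6	1	3	142
7	2	7	550
8	2	9	837
9	2	7	895
10	2	4	578
11	2	5	657
12	2	NA	NA
1	2	NA	NA
2	2	5	435
3	2	4	274
4	2	1	11
5	2	0	0
6	2	0	0
7	3	6	323
8	3	8	714
9	3	11	1691
10	3	10	1488
11	3	5	642
12	3	10	1240
1	3	NA	NA
2	3	2	104
3	3	7	516
4	3	3	191
5	3	1	23
6	3	1	51
7	4	0	0
8	4	6	465
9	4	13	852
10	4	10	888
11	4	11	1070
12	4	5	302
1	4	11	930
2	4	4	261
3	4	5	296
4	4	0	0
5	4	0	0
6	4	0	0
7	5	0	0
8	5	4	266
9	5	6	721
10	5	9	1308
11	5	10	1515
12	5	9	1094
1	5	NA	NA
2	5	NA	NA
3	5	NA	NA
4	5	NA	NA
5	5	NA	NA
6	5	NA	NA
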