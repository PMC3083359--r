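chrom	size_bp	covered_bp	n_clones
1	59305620	28385015	132
2	58009534	22677316	102
3	60907308	31396678	148
4	71658100	32427816	168
5	74451498	35726625	164
6	61647013	32747166	149
7	76918211	46016985	220
8	55568185	27732046	123
9	54736511	37568203	176
10	43467561	18729705	83
11	44116856	24200149	108
12	46853116	23019149	102
13	50748729	33185367	153
14	52930158	21972192	105
15	47237297	23826254	111
16	51890894	22116433	100
17	49469313	35083736	161
18	49271716	24262639	113
19	48708673	19679618	87
20	51884995	34768791	151
21	47572505	18049644	89
22	41415389	20094889	100
23	44714728	24485475	115
24	40403431	22721787	106
25	38768535	10635174	51
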