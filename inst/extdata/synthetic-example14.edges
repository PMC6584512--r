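1	2
1	6
2	3
2	5
3	4
3	6
4	5
4	7
4	9
4	10
5	6
6	7
7	8
7	9
8	9
8	14
9	14
10	11
10	12
11	12
12	13
13	14
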