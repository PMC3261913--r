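pair	msv5	salmon_blast	stickleback_blast	previous
1p-9qa		4	37
1qa-18qa		3	29
1qb-11qb/13qb		6	52
2p-5q	39	48	67	9
2q-12qa	1	5	33	5 (12qb)
3p-14qa			41
3q-6p	7	14	67	9
4p-8q	14	16	21	4
4q-11qb/13qb		11	58
5p-9qb		7	61
6q-15qa		3	41
7p-18qb			18
7q-17qb	33	34	35	5 (17qa)
9qc-20qa		4	36
10-16qa/23		3	112
11qa-26	2	10	54	1
12qb-22		7	56
13qa-15qb	1	7	40
14qb-27		11	57
16qb-17qa		7	19	5 (16qa-17qb)
18qa-28			14
19qa-28		4	24
19qb-29	1	3	38
20qb-24		5	52
21-25		5	51
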