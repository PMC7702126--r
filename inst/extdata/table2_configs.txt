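# Candidate relative configurations of the quinolizidine test compound.
# Columns: running id, stereodescriptor string over centers C2 C3 C4 C5 C6 N8 C23.
1 RRSSSSS
2 RSSSRSS
3 RRSSRSS
4 RRSRSSR
5 RSSRSSR
6 RSSSSSS
7 RRSRRSR
8 RSSRRSR
9 RSSRRSS
10 RRSRRSS
11 RRSSSSR
12 RSSSSSR
13 RSSRSSS
14 RRSRSSS
15 RRSSRSR
16 RSSSRSR
17 RRSSSRS
18 RSSSRRS
19 RRSSRRS
20 RRSRSRR
21 RSSRSRR
22 RSSSSRS
23 RRSRRRR
24 RSSRRRR
25 RSSRRRS
26 RRSRRRS
27 RRSSSRR
28 RSSSSRR
29 RSSRSRS
30 RRSRSRS
31 RRSSRRR
32 RSSSRRR
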