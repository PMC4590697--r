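branch	start_myr	end_myr
0	500	370
1	370	310
2	310	220
3	220	160
4	160	100
5	100	90
6	90	80
7	80	70
8	70	55
9	55	40
10	40	25
11	25	12
12	12	0
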