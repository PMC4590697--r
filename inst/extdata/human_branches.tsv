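branch	start_myr	end_myr
0	500	370
1	370	310
2	310	220
3	220	160
4	160	100
5	100	90
6	90	80
7	80	63
8	63	42
9	42	25
10	25	15
11	15	6
12	6	0
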