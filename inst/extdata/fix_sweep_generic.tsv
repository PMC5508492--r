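threshold	mean_tpr	median_tpr	mean_tnr	median_tnr
1	100	100	0	0
2	100	100	0	0
5	100	100	0.2	0.1
10	100	100	4.0	3.2
20	76.5	80	66.2	63.7
30	70.5	74.6	78.3	78.8
40	68.0	70.7	88.1	90.4
50	53.6	55	94.1	96.6
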