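threshold	mean_tpr	median_tpr	mean_tnr	median_tnr
1	98.1	100	61.3	62.2
2	97.7	100	65.3	66.7
5	97.3	100	71.8	73.6
10	96.3	100	78.5	79.2
20	91.7	100	86.9	88.1
30	88	100	91.6	92.3
40	83.6	88.9	94	94.4
50	79.4	87.5	96	96.2
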