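id,metric,plan_a,plan_b
1,d2,67.50,75.55
2,d2,65.27,89.85
3,d2,65.49,100.61
4,d2,65.61,79.61
5,d2,66.79,84.12
6,d2,66.66,85.98
7,d2,64.89,84.69
1,d98,60.00,59.41
2,d98,61.01,58.04
3,d98,58.99,67.31
4,d98,60.22,62.53
5,d98,56.39,38.79
6,d98,58.73,60.47
7,d98,61.33,67.07
1,dmean,63.13,67.35
2,dmean,63.13,73.39
3,dmean,63.12,83.74
4,dmean,63.11,74.27
5,dmean,62.99,69.08
6,dmean,62.99,75.02
7,dmean,63.13,74.75
1,hi_rtog,1.16,0.99
2,hi_rtog,1.10,1.23
3,hi_rtog,1.11,1.32
4,hi_rtog,1.11,1.05
5,hi_rtog,1.13,1.11
6,hi_rtog,1.12,1.09
7,hi_rtog,1.10,1.10
1,hi_d2d98,12.52,0.18
2,hi_d2d98,7.13,9.76
3,hi_d2d98,10.83,41.63
4,hi_d2d98,8.99,21.35
5,hi_d2d98,17.33,56.68
6,hi_d2d98,9.89,31.89
7,hi_d2d98,5.94,22.03
1,v60,98.02,96.22
2,v60,99.31,96.17
3,v60,96.07,99.51
4,v60,98.35,99.25
5,v60,93.13,85.96
6,v60,97.02,98.36
7,v60,99.89,99.98
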