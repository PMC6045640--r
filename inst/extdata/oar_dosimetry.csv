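id,oar,metric,plan_a,plan_b
1,heart,d2,61.89,62.83
2,heart,d2,45.61,43.55
3,heart,d2,55.75,58.36
4,heart,d2,63.71,70.81
5,heart,d2,62.86,72.79
6,heart,d2,56.06,60.02
7,heart,d2,29.74,32.79
1,heart,d98,0.93,0.85
2,heart,d98,0.51,0.52
3,heart,d98,6.84,6.72
4,heart,d98,2.26,2.20
5,heart,d98,0.70,0.73
6,heart,d98,0.13,0.16
7,heart,d98,0.38,0.51
1,heart,dmean,15.15,13.74
2,heart,dmean,6.66,6.38
3,heart,dmean,18.95,21.93
4,heart,dmean,20.85,23.12
5,heart,dmean,18.69,19.01
6,heart,dmean,5.46,5.91
7,heart,dmean,4.14,4.67
1,ipsilateral_lung,d2,62.44,66.80
2,ipsilateral_lung,d2,63.09,71.53
3,ipsilateral_lung,d2,64.17,88.12
4,ipsilateral_lung,d2,63.73,77.40
5,ipsilateral_lung,d2,63.31,52.63
6,ipsilateral_lung,d2,63.46,76.64
7,ipsilateral_lung,d2,63.67,78.70
1,contralateral_lung,d2,33.11,27.75
2,contralateral_lung,d2,21.38,26.76
3,contralateral_lung,d2,19.29,19.85
4,contralateral_lung,d2,22.70,23.92
5,contralateral_lung,d2,48.90,52.63
6,contralateral_lung,d2,6.58,4.66
7,contralateral_lung,d2,42.27,49.27
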