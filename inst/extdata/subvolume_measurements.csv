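id,location,age,tnm,stage,pathology,ptv_ml,ptv_low_ml,ptv_low_pct,ptv_mod_ml,ptv_mod_pct,ptv_high_ml,ptv_high_pct
1,L-U,68,T4N2M0,3b,Squamous cell carcinoma,598.47,255.70,42.73,230.20,38.46,112.57,18.81
2,L-U,68,T4N1M0,3a,Small cell carcinoma,618.05,243.16,39.34,201.39,32.59,173.50,28.07
3,L-L,60,T2N1M0,2a,Adenocarcinoma,361.53,126.03,34.86,147.22,40.72,88.28,24.42
4,R-L,40,T2N2M1,4,Small cell carcinoma,968.54,563.77,58.21,442.76,45.71,37.99,3.92
5,M,59,T4N3M1,4,Adenocarcinoma,457.75,148.72,32.49,177.70,38.82,131.33,28.69
6,L-M,73,T4N3M0,3b,Squamous cell carcinoma,394.16,228.06,57.86,112.64,28.58,53.46,13.56
7,R-U,63,T4N0M1,4,Non-small cell carcinoma,874.02,295.91,33.86,506.10,57.90,72.01,8.23
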