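group,abbrev,hr_km2,core_km2,exclusive_core_km2,pct_overlap_hr,pct_overlap_core,n_points
Bitukura,Bi,12.03,3.41,3.11,43.45,8.62,162
Kyagurilo,Ky,15.01,4.46,4.17,34.83,6.59,394
Busingye,Bu,7.37,2.33,0.88,94.79,62.09,204
Mishaya,Mi,6.42,1.94,0.62,91.69,67.87,202
Kahungye,Kah,8.90,3.15,0.75,93.24,76.09,191
Bweza,Bw,7.66,2.51,2.47,40.60,1.93,128
Kakono,Kak,9.90,3.49,3.44,30.95,1.39,105
Mubare,Mu,4.50,1.10,1.10,65.52,0.05,205
Habinjanya,Ha,14.01,3.88,3.88,17.18,0.01,195
Rushegura,Ru,6.39,1.47,1.47,9.68,0,198
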