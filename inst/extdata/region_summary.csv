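region,map_pct,c_thr_pct,rec_pct,prec_pct,f1_pct
Atlantic/Mediterranean,87.7,67.4,80.1,88.0,83.9
Pacific,90.1,44.8,82.2,84.9,83.5
Arctic/Baltic,90.1,55.4,80.7,83.7,82.2
Indian/South China,89.0,64.8,77.5,84.4,80.8
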