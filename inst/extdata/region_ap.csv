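region,species,ap_pct
Atlantic/Mediterranean,A. aurita,81.2
Atlantic/Mediterranean,C. branchi,77.3
Atlantic/Mediterranean,C. hysoscella,79.6
Atlantic/Mediterranean,C. quinquecirrha,91.3
Atlantic/Mediterranean,C. tuberculata,91.1
Atlantic/Mediterranean,C. capillata,94.7
Atlantic/Mediterranean,C. lamarckii,93.5
Atlantic/Mediterranean,P. noctiluca,74.6
Atlantic/Mediterranean,R. luteum,79.8
Atlantic/Mediterranean,R. pulmo,96.9
Atlantic/Mediterranean,S. meleagris,93.1
Atlantic/Mediterranean,T. ohboya,98.9
Pacific,A. aurita,82.5
Pacific,C. achlyos,99.3
Pacific,C. fuscescens,83.4
Pacific,C. capillata,99.5
Pacific,N. nomurai,91.6
Pacific,P. noctiluca,78.1
Pacific,S. meleagris,96.0
Arctic/Baltic,A. aurita,81.5
Arctic/Baltic,C. fuscescens,83.2
Arctic/Baltic,C. capillata,97.4
Arctic/Baltic,C. lamarckii,98.4
Indian/South China,A. aurita,82.4
Indian/South China,C. quinquecirrha,96.9
Indian/South China,N. nomurai,97.5
Indian/South China,P. noctiluca,79.2
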