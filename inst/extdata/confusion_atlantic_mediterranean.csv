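species,A. aurita,C. branchi,C. hysoscella,C. quinquecirrha,C. tuberculata,C. capillata,C. lamarckii,P. noctiluca,R. luteum,R. pulmo,S. meleagris,T. ohboya
A. aurita,99.5,0.1,-,-,-,-,-,-,-,0.1,0.3,-
C. branchi,2.4,93.5,-,-,-,-,-,-,-,-,-,4.1
C. hysoscella,-,-,93.8,-,0.3,0.3,-,5.2,-,0.3,-,-
C. quinquecirrha,-,-,-,95.9,-,-,-,4.1,-,-,-,-
C. tuberculata,-,-,0.9,-,95.3,-,-,0.6,-,1.8,1.5,-
C. capillata,-,-,-,-,0.5,97.4,1.5,-,-,0.5,-,-
C. lamarckii,-,-,-,-,-,3.3,95.1,-,-,1.6,-,-
P. noctiluca,0.3,-,-,-,-,-,-,99.4,-,0.3,-,-
R. luteum,-,-,-,-,-,-,-,-,81.1,17.9,-,0.9
R. pulmo,0.3,-,-,-,-,-,-,0.3,0.3,98.6,0.3,-
S. meleagris,-,-,-,-,-,-,-,-,-,3.9,96.1,-
T. ohboya,-,-,-,-,-,-,-,0.4,-,-,-,99.6
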