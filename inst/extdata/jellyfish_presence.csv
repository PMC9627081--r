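species,Atlantic/Mediterranean,Pacific,Arctic/Baltic,Indian/South China
Aurelia aurita,x,x,x,x
Carybdea branchi,x,-,-,-
Chrysaora achlyos,-,x,-,-
Chrysaora fuscescens,-,x,x,-
Chrysaora hysoscella,x,-,-,-
Chrysaora quinquecirrha,x,-,-,x
Cotylorhiza tuberculata,x,-,-,-
Cyanea capillata,x,x,x,-
Cyanea lamarckii,x,-,x,-
Nemopilema nomurai,-,x,-,x
Pelagia noctiluca,x,x,-,x
Rhizostoma luteum,x,-,-,-
Rhizostoma pulmo,x,-,-,-
Stomolophus meleagris,x,x,-,-
Tamoya ohboya,x,-,-,-
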