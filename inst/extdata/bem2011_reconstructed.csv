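study,d,se
"exp1 detection of erotic stimuli",0.25,0.10155
"exp2 avoidance of negative stimuli",0.20,0.08246
"exp3 retroactive priming I",0.26,0.10324
"exp4 retroactive priming II",0.23,0.10182
"exp5 retroactive habituation I",0.22,0.10120
"exp6 retroactive habituation II",0.15,0.08211
"exp7 retroactive induction of boredom",0.09,0.07085
"exp8 retroactive facilitation of recall I",0.19,0.10090
"exp9 retroactive facilitation of recall II",0.42,0.14753
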