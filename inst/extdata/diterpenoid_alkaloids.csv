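name,formula,adduct,observed_mz,reported_ppm,activity_score
Columbianine,C22H35NO5,[M+Na]+,416.2431,4.3,0.04
Ignavine,C27H31NO5,[M+H]+,450.2295,3.3,0.07
Chasmanine,C25H41NO6,[M+Na]+,474.2835,0.6,0.07
10-OH-hypaconitine,C33H45NO11,[M+H]+,632.3106,5.5,0.06
8-O-Azeloyl-14-benzoylaconine,C41H59NO13,[M+H]+,774.4071,0.8,0.04
3-Acetyl-8-ole-benzoylaconine,C52H79NO12,[M+Na]+,944.5516,1.7,0.23
1-O-Benzoylkarasamine,C30H41NO5,[M+Na]+,518.2877,-1.0,0.04
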