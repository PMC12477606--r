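"mutant_id","category","aa_number","code","aa_change"
"1","Universal",597,"C.S8.7","D-A"
"2","Universal",758,"C.L23.10","G-A"
"3","Universal",714,"C.L20.6","R-A"
"4","Universal",733,"C.L21.16","G-R"
"5","Eukaryota",790,"C.L25.3","Y-A"
"6","Eukaryota",710,"C.L20.2","R-A"
"7","Eukaryota",600,"C.L14.1","H-A"
"8CANCER","Eukaryota",757,"C.L23.6","Q-L"
"9","Eukaryota",673,"C.L18.5","E-A"
"9CANCER","Eukaryota",673,"C.L18.5","E-K"
"10CANCER","AGO-like",812,"C.H10.13","R-W"
"11","AGO-like",792,"C.L25.5","R-A"
"12","AGO-like",804,"C.H10.5","Y-A"
"13","AGO-like",753,"C.L23.2","H-A"
"14","Animal",358,"N.H7.2","D-A"
"14CANCER","Animal",358,"N.H7.2","D-G"
"20","Universal",573,"C.L11.2","G-W"
"21","Universal",215,"N.S12.3","L-F"
"22","Eukaryota",700,"C.L19.5","P-S"
"23","Eukaryota",679,"C.H8.5","V-K"
"24","AGO-like",193,"N.S10.3","G-W"
"25","Animal",622,"C.L15.5","P-S"
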