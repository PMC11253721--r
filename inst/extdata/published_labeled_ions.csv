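study,rt,mz,adduct,neutral_printed
broccoli_urine,23,426.1023,[M-H+FA]-,381.105
broccoli_urine,23,404.0952,[M+Na]+,381.105
broccoli_urine,21.18,366.0817,[M-H]-,367.0892
broccoli_urine,21.18,390.0787,[M+Na]+,367.0892
broccoli_urine,20.7,510.1234,[M-H]-,511.1314
broccoli_urine,20.7,512.1394,[M+H]+,511.1314
collard_urine,20,225.0765,[M-H]-,226.0835
collard_urine,20,227.0907,[M+H]+,226.0835
collard_urine,20,249.0727,[M+Na]+,226.0835
collard_plasma,6.36,130.0867,[M-H]+,131.0939
collard_plasma,6.36,132.1011,[M+H]+,131.0939
collard_plasma,24.8,311.2229,[M-H]+,312.2291
collard_plasma,24.8,295.2247,[M+H-H2O]+,312.2291
collard_plasma,24.8,313.2372,[M-H]+,314.2426
collard_plasma,24.8,297.2375,[M+H-H2O]+,314.2426
collard_plasma,24.8,333.2044,[M-H]-,334.2113
collard_plasma,24.8,335.2181,[M+H]+,334.2113
collard_plasma,24.8,335.2199,[M-H]-,336.2254
collard_plasma,24.8,403.2071,[M-H+HCOONa]-,336.2254
collard_plasma,24.8,337.2327,[M+H]+,336.2254
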