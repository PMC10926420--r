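comparison,block,SSr,SSc,DF1,DF2,F_printed
CT vs US males,linear,195.573,194.732,2,592,1.28
CT vs US males,quadratic,161.661,161.147,2,588,0.93
CT vs US males,correlational,155.836,155.815,1,586,0.08
CT vs US females,linear,168.699,166.744,2,592,3.47
CT vs US females,quadratic,143.904,142.843,2,588,2.18
CT vs US females,correlational,139.673,139.558,1,586,0.48
CT females vs CT males,linear,133.874,130.844,2,592,5.95
CT females vs CT males,quadratic,100.026,98.955,2,588,3.18
CT females vs CT males,correlational,94.123,94.113,1,586,0.03
US females vs US males,linear,232.207,230.442,2,592,2.26
US females vs US males,quadratic,206.340,205.036,2,588,1.87
US females vs US males,correlational,201.366,201.260,1,586,0.31
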