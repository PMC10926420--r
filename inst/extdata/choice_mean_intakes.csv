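line,sex,protein_mg,carb_mg
CT,F,15.65,57.33
CT,M,15.46,55.45
US,F,19.93,64.39
US,M,20.06,64.55
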