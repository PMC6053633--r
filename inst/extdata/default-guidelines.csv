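# Default sediment quality guidelines, mg/kg dry weight.
# TEL/PEL: freshwater threshold and probable effect levels, Smith et al. (1996),
#   J. Great Lakes Res. 22:624-638 (the Canadian freshwater SQG compilation).
# SEL: severe effect levels, Persaud, Jaagumagi & Hayton (1993), Guidelines for
#   the Protection and Management of Aquatic Sediment Quality in Ontario.
# User-overridable: pass any file with the same columns to read_guidelines().
metal,tel,pel,sel
Cd,0.596,3.53,10
Cr,37.3,90,110
Cu,35.7,197,110
Ni,18,36,75
Pb,35,91.3,250
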