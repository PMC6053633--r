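# Default constants for the classical contamination indices.
# background: average-shale crustal reference concentrations, mg/kg dry weight,
#   Turekian & Wedepohl (1961), Geol. Soc. Am. Bull. 72:175-192.
# tr: dimensionless toxic-response factors, Hakanson (1980), Water Res.
#   14:975-1001 (Cd 30, Pb 5, Cu 5, Cr 2); Ni assigned the conventional 5.
# User-overridable: pass any file with the same columns to read_constants().
metal,background,tr
Cd,0.3,30
Cr,90,2
Cu,45,5
Ni,68,5
Pb,20,5
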