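# Two retained rotated principal components per site from correlation-matrix PCA of
# the five-metal sediment concentration data of the bundled case-study survey:
# loadings per metal, eigenvalue, % variability and cumulative % per component.
site,component,Cd,Cr,Cu,Ni,Pb,eigenvalue,variability,cumulative
DOU,PC1,0.634,0.16,0.75,0.125,-0.401,1.705,34.108,34.108
DOU,PC2,0.452,0.345,-0.144,0.558,0.587,1.601,32.022,66.13
OKT,PC1,0.234,-0.786,0.943,0.368,-0.817,2.366,47.314,47.314
OKT,PC2,0.936,0.508,-0.002,-0.095,-0.265,1.214,24.275,71.589
STB,PC1,0.953,0.439,0.907,0.623,-0.06,2.317,46.337,46.337
STB,PC2,0.114,-0.635,-0.252,0.716,0.783,1.605,32.11,78.447
QUR,PC1,0.576,-0.682,0.821,0.467,0.662,2.128,42.565,42.565
QUR,PC2,0.734,0.459,-0.149,0.865,-0.59,1.868,37.36,79.925
QUE,PC1,0.484,0.485,-0.832,0.522,0.913,2.268,45.365,45.365
QUE,PC2,-0.758,0.708,-0.068,-0.431,0.21,1.311,26.226,71.591
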