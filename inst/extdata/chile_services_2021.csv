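service,population,school_prev,school_lo,school_hi,updated_prev,updated_lo,updated_hi
Aconcagua,46840,0.43,0.37,0.50,1.28,1.21,1.34
Aisen,19890,0.75,0.63,0.90,1.60,1.47,1.73
Antofagasta,119378,0.83,0.77,0.88,1.67,1.61,1.74
Araucania Norte,36651,0.30,0.24,0.38,1.15,1.08,1.21
Araucania Sur,132242,0.37,0.34,0.41,1.22,1.16,1.28
Arauco,31318,0.72,0.62,0.82,1.56,1.46,1.66
Arica,44609,0.61,0.54,0.70,1.46,1.38,1.54
Atacama,58743,0.31,0.27,0.37,1.16,1.10,1.22
Biobio,71411,0.42,0.37,0.47,1.27,1.20,1.33
Chiloe,30908,0.43,0.36,0.52,1.28,1.20,1.36
Concepcion,109502,0.77,0.72,0.83,1.62,1.56,1.68
Coquimbo,141152,0.40,0.36,0.43,1.24,1.18,1.31
Iquique,69935,0.43,0.38,0.49,1.28,1.22,1.34
Magallanes,28031,0.83,0.72,0.96,1.68,1.56,1.80
Maule,182352,0.30,0.28,0.33,1.15,1.09,1.21
Metropolitano Central,122576,0.42,0.38,0.46,1.26,1.20,1.33
Metropolitano Norte,180230,0.29,0.26,0.31,1.13,1.07,1.20
Metropolitano Occidente,277282,0.34,0.32,0.36,1.19,1.12,1.25
Metropolitano Oriente,182798,0.30,0.27,0.33,1.15,1.08,1.21
Metropolitano Sur,200984,0.40,0.37,0.43,1.25,1.18,1.31
Metropolitano Sur Oriente,236817,0.36,0.34,0.39,1.21,1.15,1.27
O'Higgins,161335,0.42,0.39,0.46,1.27,1.21,1.34
Osorno,40266,0.43,0.37,0.51,1.28,1.21,1.35
Reloncavi,79767,0.42,0.37,0.47,1.26,1.20,1.33
Talcahuano,54678,0.81,0.74,0.90,1.66,1.58,1.74
Valdivia,66206,0.30,0.26,0.35,1.15,1.08,1.21
Valparaiso,78598,0.68,0.62,0.74,1.52,1.46,1.59
Vina del Mar,172456,0.66,0.62,0.70,1.51,1.44,1.57
Nuble,79351,1.29,1.21,1.37,2.13,2.05,2.21
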