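region,n,measure,category,mean,sd
Global North,54,access,economic,0.45,0.23
Global North,54,access,social,0.44,0.32
Global North,54,access,environmental,0.43,0.26
Global North,54,gini,economic,0.47,0.11
Global North,54,gini,social,0.78,0.15
Global North,54,gini,environmental,0.27,0.11
Global South,112,access,economic,0.36,0.26
Global South,112,access,social,0.22,0.21
Global South,112,access,environmental,0.30,0.27
Global South,112,gini,economic,0.58,0.11
Global South,112,gini,social,0.85,0.10
Global South,112,gini,environmental,0.39,0.13
Europe,40,access,economic,0.38,0.15
Europe,40,access,social,0.39,0.29
Europe,40,access,environmental,0.47,0.25
Europe,40,gini,economic,0.46,0.09
Europe,40,gini,social,0.81,0.13
Europe,40,gini,environmental,0.25,0.09
Asia,46,access,economic,0.53,0.30
Asia,46,access,social,0.30,0.26
Asia,46,access,environmental,0.21,0.21
Asia,46,gini,economic,0.54,0.13
Asia,46,gini,social,0.81,0.16
Asia,46,gini,environmental,0.43,0.14
North America,16,access,economic,0.41,0.27
North America,16,access,social,0.35,0.29
North America,16,access,environmental,0.44,0.23
North America,16,gini,economic,0.54,0.10
North America,16,gini,social,0.80,0.11
North America,16,gini,environmental,0.38,0.10
South America,12,access,economic,0.48,0.24
South America,12,access,social,0.44,0.33
South America,12,access,environmental,0.56,0.23
South America,12,gini,economic,0.59,0.05
South America,12,gini,social,0.82,0.06
South America,12,gini,environmental,0.41,0.10
Oceania,4,access,economic,0.32,0.31
Oceania,4,access,social,0.34,0.38
Oceania,4,access,environmental,0.95,0.11
Oceania,4,gini,economic,0.49,0.07
Oceania,4,gini,social,0.73,0.08
Oceania,4,gini,environmental,0.27,0.10
Africa,48,access,economic,0.24,0.18
Africa,48,access,social,0.13,0.11
Africa,48,access,environmental,0.24,0.22
Africa,48,gini,economic,0.61,0.12
Africa,48,gini,social,0.87,0.09
Africa,48,gini,environmental,0.34,0.12
Global,166,access,economic,0.39,0.25
Global,166,access,social,0.29,0.27
Global,166,access,environmental,0.35,0.27
Global,166,gini,economic,0.55,0.12
Global,166,gini,social,0.83,0.12
Global,166,gini,environmental,0.35,0.14
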