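term,sumsq,meansq,df,statistic,p.value,etasq,partial.etasq,omegasq,partial.omegasq,cohens.f,power
(Intercept),170.18961,170.18961,1,11614.34465,0,0.97433,0.97876,0.97416,0.97802,6.78886,1
Genotype,0.00371,0.00371,1,0.25317,0.61529,0.00002,0.001,-0.00006,-0.00287,0.0317,0.07948
mtDNA,0.00024,0.00024,1,0.01623,0.89874,0,0.00006,-0.00008,-0.00378,0.00802,0.05186
Treatment,0.60305,0.60305,1,41.15459,0,0.00345,0.14039,0.00337,0.13334,0.40412,1
Genotype:mtDNA,0.07883,0.07883,1,5.3799,0.02117,0.00045,0.0209,0.00037,0.0165,0.14611,0.64051
Genotype:Treatment,0.04789,0.04789,1,3.26796,0.07184,0.00027,0.0128,0.00019,0.00861,0.11388,0.43969
mtDNA:Treatment,0.00275,0.00275,1,0.18779,0.66513,0.00002,0.00074,-0.00007,-0.00312,0.0273,0.07178
Genotype:mtDNA:Treatment,0.05487,0.05487,1,3.74434,0.05411,0.00031,0.01464,0.00023,0.01041,0.1219,0.49021
Residuals,3.69266,0.01465,252,,,,,,,,
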