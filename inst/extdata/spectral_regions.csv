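ppm_lo,ppm_hi,assignment,attribution
5.20,5.50,CH=CH,all unsaturated fatty acids
5.00,5.20,CH-OCOR,triacylglycerols
4.00,4.30,CH2-OCOR,triacylglycerols
2.60,2.80,CH=CH-CH2-CH=CH,linoleic and linolenic chains
2.20,2.40,CH2-COOH,all acyl chains
1.90,2.10,CH2-CH=CH,all unsaturated fatty acids
1.50,1.70,CH2-CH2-COOH,all acyl chains
1.05,1.40,(CH2)n,all acyl chains
0.85,1.00,CH=CH-CH2-CH3,linolenic acid
0.70,0.85,CH2-CH2-CH2-CH3,all acyl chains except linolenyl
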