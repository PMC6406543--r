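part,direction,number,mirna,gene,localization,log2fc,p,p_adj
A,down,1,hsa-miR-3647-3p,SNORD111B,16q22.1,-4.15,1.04E-05,0.0017
A,down,2,hsa-miR-181a*,MIR181A2,9q33.3,-1.50,5.06E-06,0.0017
A,down,3,hsa-miR-181a,MIR181A2,9q33.3,-1.27,1.73E-05,0.0017
A,down,4,hsa-miR-181b,MIR181B1,1q32.1,-1.32,8.69E-06,0.0017
A,down,5,hsa-miR-3607-3p,SNORD138,5q14.3,-3.41,0.00040,0.017
A,down,6,hsa-miR-330-5p,MIR330,19q13.32,-1.15,0.00075,0.021
A,up,1,hsa-miR-431,MIR431,14q32.2,1.86,1.21E-05,0.0017
A,up,2,hsa-miR-432,MIR432,14q32.2,1.71,1.73E-05,0.0017
A,up,3,hsa-miR-376c,MIR376C,14q32.31,1.86,2.53E-05,0.0021
A,up,4,hsa-miR-656,MIR656,14q32.31,2.37,3.47E-05,0.0025
A,up,5,hsa-miR-409-5p,MIR409,14q32.31,5.99,9.94E-05,0.0064
A,up,6,hsa-miR-411,MIR411,14q32.31,1.54,0.00011,0.0065
A,up,7,hsa-miR-376a,MIR376A-1,14q32.31,1.99,0.00015,0.0077
A,up,8,hsa-miR-377,MIR377,14q32.31,2.62,0.00016,0.0077
A,up,9,hsa-miR-127-3p,MIR127,14q32.2,1.50,0.00023,0.010
A,up,10,hsa-miR-410,MIR410,14q32.31,1.29,0.00047,0.018
A,up,11,hsa-miR-379,MIR379,14q32.31,1.69,0.00059,0.020
A,up,12,hsa-miR-758,MIR758,14q32.31,1.51,0.00065,0.020
A,up,13,hsa-miR-889,MIR889,14q32.31,1.47,0.00064,0.020
A,up,14,hsa-miR-337-3p,MIR337,14q32.2,2.25,0.00066,0.020
A,up,15,hsa-miR-485-5p,MIR485,14q32.31,1.88,0.00075,0.021
A,up,16,hsa-miR-485-3p,MIR485,14q32.31,1.47,0.00093,0.024
A,up,17,hsa-miR-136*,MIR136,14q32.2,1.39,0.00093,0.024
A,up,18,hsa-miR-433,MIR433,14q32.2,1.65,0.0012,0.030
A,up,19,hsa-miR-493,MIR493,14q32.2,1.31,0.0015,0.032
A,up,20,hsa-miR-495,MIR495,14q32.31,1.50,0.0015,0.032
A,up,21,hsa-miR-337-5p,MIR337,14q32.2,2.02,0.0018,0.038
A,up,22,hsa-miR-409-3p,MIR409,14q32.31,1.15,0.0020,0.040
A,up,23,hsa-miR-376b,MIR376B,14q32.31,2.23,0.0021,0.040
A,up,24,hsa-miR-370,MIR370,14q32.31,1.77,0.0022,0.041
A,up,25,hsa-miR-134,MIR134,14q32.31,1.32,0.0023,0.041
A,up,26,hsa-miR-381,MIR381,14q32.31,1.63,0.0034,0.048
B,up,1,hsa-miR-1,MIR1-1/MIR1-2,20q13.33/18q11.2,3.82,3.58E-06,0.002
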