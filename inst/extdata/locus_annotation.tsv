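mirna	gene	band
hsa-miR-3647-3p	SNORD111B	16q22.1
hsa-miR-181a*	MIR181A2	9q33.3
hsa-miR-181a	MIR181A2	9q33.3
hsa-miR-181b	MIR181B1	1q32.1
hsa-miR-3607-3p	SNORD138	5q14.3
hsa-miR-330-5p	MIR330	19q13.32
hsa-miR-431	MIR431	14q32.2
hsa-miR-432	MIR432	14q32.2
hsa-miR-376c	MIR376C	14q32.31
hsa-miR-656	MIR656	14q32.31
hsa-miR-409-5p	MIR409	14q32.31
hsa-miR-411	MIR411	14q32.31
hsa-miR-376a	MIR376A-1	14q32.31
hsa-miR-377	MIR377	14q32.31
hsa-miR-127-3p	MIR127	14q32.2
hsa-miR-410	MIR410	14q32.31
hsa-miR-379	MIR379	14q32.31
hsa-miR-758	MIR758	14q32.31
hsa-miR-889	MIR889	14q32.31
hsa-miR-337-3p	MIR337	14q32.2
hsa-miR-485-5p	MIR485	14q32.31
hsa-miR-485-3p	MIR485	14q32.31
hsa-miR-136*	MIR136	14q32.2
hsa-miR-433	MIR433	14q32.2
hsa-miR-493	MIR493	14q32.2
hsa-miR-495	MIR495	14q32.31
hsa-miR-337-5p	MIR337	14q32.2
hsa-miR-409-3p	MIR409	14q32.31
hsa-miR-376b	MIR376B	14q32.31
hsa-miR-370	MIR370	14q32.31
hsa-miR-134	MIR134	14q32.31
hsa-miR-381	MIR381	14q32.31
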