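site	environment	fraction	dmspMean	dmspSd	unit
H12	YS-sediment	total	62.5	4.8	nmol/g
HS5	YS-sediment	total	72.2	8.6	nmol/g
H25	YS-sediment	total	25.2	9.3	nmol/g
B41	BS-sediment	total	26.9	4.8	nmol/g
B45	BS-sediment	total	9.5	1.4	nmol/g
B47	BS-sediment	total	13.6	1.0	nmol/g
B50	BS-sediment	total	35.4	2.5	nmol/g
TVG5-3	OT-sediment	total	6.2	0.3	nmol/g
TVG5-3	OT-polymetallic-sulfide	total	6.5	0.6	nmol/g
TVG11-2	OT-sediment	total	6.4	2.6	nmol/g
TVG11-2	OT-polymetallic-sulfide	total	6.6	2.8	nmol/g
T1	OT-sediment	total	6.8	2.3	nmol/g
F8	seawater	DMSPd	4.6	NA	nmol/L
F8	seawater	DMSPp	18.0	NA	nmol/L
G1	seawater	DMSPd	10.7	NA	nmol/L
G1	seawater	DMSPp	32.5	NA	nmol/L
F3	seawater	DMSPd	10.0	NA	nmol/L
F3	seawater	DMSPp	25.0	NA	nmol/L
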