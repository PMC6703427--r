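# Standard Gibbs energies (and enthalpies where available) of formation at 298.15 K.
# Units: kJ/mol. Standard states: gas 1 bar, aqueous 1 M, liquid/solid pure phase.
# Small-molecule values follow the classic anaerobic-bioenergetics compilation
# (Thauer/Amend-Shock style); liquid n-alkane values follow CRC handbook liquid
# values for C5-C10 extended by group additivity (+5.4 kJ/mol per CH2) beyond C10.
id	name	formula	charge	phase	dGf0_kJ_mol	dHf0_kJ_mol	source
h2o	water	H2O	0	liquid	-237.18	-285.83	Thauer-style compilation
h_plus	proton	H	1	aqueous	0	0	convention (pH scale)
e_minus	formal electron		-1	carrier	0	0	convention
ch4_g	methane (gas)	CH4	0	gas	-50.75	-74.81	Thauer-style compilation
ch4_aq	methane (dissolved)	CH4	0	aqueous	-34.39	-89.04	Amend-Shock-style compilation
co2_g	carbon dioxide (gas)	CO2	0	gas	-394.36	-393.51	Thauer-style compilation
co2_aq	carbon dioxide (dissolved)	CO2	0	aqueous	-386.02	-413.80	Thauer-style compilation
h2_g	dihydrogen (gas)	H2	0	gas	0	0	convention (reference state)
h2_aq	dihydrogen (dissolved)	H2	0	aqueous	17.57	-4.2	Amend-Shock-style compilation
acetate	acetate	C2H3O2	-1	aqueous	-369.41	-486.01	Thauer-style compilation
rh	H4MPT methyl carrier, free (R-H)	RH	0	carrier	NA	NA	bookkeeping species
rch3	H4MPT methyl carrier, loaded (R-CH3)	RCH3	0	carrier	NA	NA	bookkeeping species
c2h6	ethane (gas)	C2H6	0	gas	-32.0	-84.0	gas-phase handbook value
c3h8	propane (gas)	C3H8	0	gas	-23.4	-103.8	gas-phase handbook value
c4h10	n-butane (gas)	C4H10	0	gas	-17.0	-125.7	gas-phase handbook value
c5h12	n-pentane (liquid)	C5H12	0	liquid	-9.2	-173.5	CRC-style liquid value
c6h14	n-hexane (liquid)	C6H14	0	liquid	-4.0	-198.7	CRC-style liquid value
c7h16	n-heptane (liquid)	C7H16	0	liquid	1.3	-224.2	CRC-style liquid value
c8h18	n-octane (liquid)	C8H18	0	liquid	6.4	-250.1	CRC-style liquid value
c9h20	n-nonane (liquid)	C9H20	0	liquid	11.8	-274.7	CRC-style liquid value
c10h22	n-decane (liquid)	C10H22	0	liquid	17.4	-300.9	CRC-style liquid value
c11h24	n-undecane (liquid)	C11H24	0	liquid	22.8	-327.2	group additivity from C10
c12h26	n-dodecane (liquid)	C12H26	0	liquid	28.2	-352.1	group additivity from C10
c13h28	n-tridecane (liquid)	C13H28	0	liquid	33.6	-378.3	group additivity from C10
c14h30	n-tetradecane (liquid)	C14H30	0	liquid	39.0	-403.0	group additivity from C10
c15h32	n-pentadecane (liquid)	C15H32	0	liquid	44.4	-428.8	group additivity from C10
c16h34	n-hexadecane (liquid)	C16H34	0	liquid	49.8	-456.1	group additivity from C10
c17h36	n-heptadecane (liquid)	C17H36	0	liquid	55.2	-480.9	group additivity from C10
c18h38	n-octadecane (liquid)	C18H38	0	liquid	60.6	-507.1	group additivity from C10
c19h40	n-nonadecane (liquid)	C19H40	0	liquid	66.0	-531.6	group additivity from C10
c20h42	n-eicosane (liquid)	C20H42	0	liquid	71.4	-556.6	group additivity from C10
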