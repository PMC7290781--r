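# Printed cysteine-rich peptide scaffolds (scaffold string, mature length, TPM).
# The six-cysteine row "x_18Cx_6Cx_3CCx_8Cx_24Cx_7" is stored with the corrected
# token "CCx_8" (printed as "CC_8_"); only the corrected form satisfies the
# length identity (sum of spacers + cysteines = 72).
n_cys	scaffold	length	tpm
4	x_8CCx_1Cx_19Cx_5	37	772
4	x_1CCx_34Cx_1Cx_1	41	18.4
4	x_5CCx_1Cx_16Cx_14	40	16.5
4	CCx_23Cx_7Cx_6	40	13
4	x_14CCx_11Cx_7Cx_33	69	10.8
4	CCx_1Cx_27Cx_12	44	7.1
4	x_3CCx_6Cx_15Cx_9	37	2.2
4	x_6CCx_7Cx_11Cx_8	36	0.76
4	x_8CCx_5Cx_12Cx_6	35	0.3
6	Cx_6Cx_5CCx_4Cx_6Cx_29	56	43.8
6	x_18Cx_6Cx_3CCx_8Cx_24Cx_7	72	9.3
6	x_7Cx_8Cx_21CCx_5Cx_22Cx_20	89	5.9
6	Cx_6Cx_5CCx_4Cx_6Cx_29	56	3.9
6	x_8Cx_6Cx_5CCx_4Cx_6Cx_25	60	3.4
6	x_8Cx_6Cx_5CCx_4Cx_6Cx_7	42	2.6
8	x_14Cx_9Cx_3Cx_5Cx_5CCx_3Cx_4Cx_26	77	1.76
10	x_10Cx_5Cx_4CCx_11Cx_9Cx_28Cx_1Cx_5Cx_6Cx_1	90	12.67
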