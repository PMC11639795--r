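peptide	model	unbound	bound
pep-1	15	1152.33	744.30
pep-2	22	1152.33	799.17
pep-3	60	1152.33	772.72
pep-4	32	1152.33	733.67
pep-5	1	1152.33	751.34
pep-6	10	1152.33	691.66
pep-7	6	1152.33	725.49
pep-8	25	1152.33	727.16
pep-9	43	1152.33	711.58
pep-10	34	1152.33	735.50
pep-11	3	1152.33	708.99
pep-12	22	1152.33	736.32
pep-13	9	1152.33	693.15
pep-14	2	1152.33	719.97
pep-15	7	1152.33	747.69
pep-16	11	1152.33	789.21
pep-17	26	1152.33	749.36
pep-18	4	1152.33	753.00
pep-19	15	1152.33	763.70
pep-20	38	1152.33	754.82
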