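# SYNTHETIC ranked calibration fixture: plausible percent-of-control values
# filled in for a nine-member EF1a panel; only for examples and tests of
# ranking/selection logic, not measured data.
hairpin_id	delta_g_kcal_mol	promoter	mean_percent	sem	n
control	NA	EF1a	100	0	3
HP02	-27.8	EF1a	72.4	3.1	3
HP05	-29.5	EF1a	63.8	2.7	3
HP08	-31.2	EF1a	49.6	2.2	3
HP11	-32.9	EF1a	41.3	1.9	3
HP14	-34.5	EF1a	30.7	1.6	3
HP17	-36.1	EF1a	22.5	1.2	3
HP19	-37.3	EF1a	15.8	0.9	3
HP21	-38.4	EF1a	11.2	0.7	3
HP23	-39.6	EF1a	6.9	0.4	3
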