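peptide_id	sequence	relative_affinity	delta_g	pbtot	pbtot_sd	pp_score
APP_native	QNGYENPTYKFFE	1	-8.906	-80.42	8.87	-6.05
APP_E5A	QNGYANPTYKFFE	0.19	-7.901	-75.11	8.73	-3.08
APP_F11A	QNGYENPTYKAFE	0.1	-7.491	-76.47	7.42	-0.87
APP_F12A	QNGYENPTYKFAE	0.11	-7.551	-69.06	10.15	-2.51
APP_E13A	QNGYENPTYKFFA	0.56	-8.541	-71.91	9.10	-3.25
APP_10mer	GYENPTYKFF	0.07	-7.324	-58.32	5.88	-2.43
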