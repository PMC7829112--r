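asv_id	SD_1	SD_2	WD_1	WD_2	WD_3
asv1	500	250	0	0	0
asv2	500	750	400	200	300
asv3	0	0	400	600	500
asv4	0	0	200	200	200
asv5	1000	1000	1000	1000	1000
tox1	100	100	100	100	100
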