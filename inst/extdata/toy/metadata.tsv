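sample_id	group
SD_1	SD
SD_2	SD
WD_1	WD
WD_2	WD
WD_3	WD
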