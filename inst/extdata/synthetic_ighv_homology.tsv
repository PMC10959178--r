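case_id	ighv_homology
synth01	68
synth02	71
synth03	74
synth04	78
synth05	80
synth06	83
synth07	85
synth08	86
synth09	87
synth10	87
synth11	88
synth12	89
synth13	90
synth14	91
synth15	92
synth16	93
synth17	95
synth18	96
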