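subject_id	n_reads	group
YSLV3	1199	OLV_YSLV
OLV_YSLV_other	2138	OLV_YSLV
Mavirus_ALM_Sputnik_Zamilon	582	distant
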