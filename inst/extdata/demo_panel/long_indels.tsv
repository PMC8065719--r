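target_id	segment_id	kind	event_sequence	anchor_pos
EGFR_longins	seg_EGFR_1	long_insertion	GCAACTCTGGAA	250
EGFR_longdel	seg_EGFR_2	long_deletion	TCTGATGCGCCG	250
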