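organ	metric	cmp	value	value_high	relative
target	D95	ge	1	NA	TRUE
target	V95	gt	0.95	NA	FALSE
lung_pneumonitis	Dmean	lt	15	20	FALSE
lung_pneumonitis_hetero	Dmean	lt	15	20	FALSE
esophagus_perforation	Dmean	lt	34	NA	FALSE
esophagus_perforation	D2	lt	69	NA	FALSE
heart_pericarditis	Dmean	lt	26	NA	FALSE
heart_pericarditis	D2	lt	30	NA	FALSE
spinal_cord	D2	lt	50	NA	FALSE
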