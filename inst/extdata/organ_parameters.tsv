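organ	organ_class	d50	a	gamma50	gamma50_provenance	endpoint	eud_max_1pct	eud_max_5pct
target	target	50	-10	2	assumed-typical-tumor-slope	control	NA	NA
lung_pneumonitis	parallel	24.5	1.2	2	derived-from-1pct-column	pneumonitis	13.9	17.1
lung_pneumonitis_hetero	parallel	30.8	1.01	2	derived-from-1pct-column	pneumonitis	17.4	21.4
esophagus_perforation	serial	68	18	4	derived-from-1pct-column	perforation	51.1	56.5
esophagus_esophagitis	serial	51	2.27	4	derived-from-1pct-column	acute esophagitis grade 2-3	38.4	42.4
heart_pericarditis	serial	48	3.1	3	derived-from-1pct-column	pericarditis	32.8	37.5
spinal_cord	serial	66.5	20	4	derived-from-1pct-column	necrosis	49.9	55.3
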