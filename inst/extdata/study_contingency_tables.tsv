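analysis	group	category	count
promoter_complexity_pmsg	affected	single	650
promoter_complexity_pmsg	affected	multi	411
promoter_complexity_pmsg	neutral	single	1104
promoter_complexity_pmsg	neutral	multi	662
promoter_complexity_hcg	affected	single	2237
promoter_complexity_hcg	affected	multi	1305
promoter_complexity_hcg	neutral	single	3196
promoter_complexity_hcg	neutral	multi	1405
stop_last_exon_pmsg	affected	last	223
stop_last_exon_pmsg	affected	not_last	22
stop_last_exon_pmsg	neutral	last	360
stop_last_exon_pmsg	neutral	not_last	33
stop_last_exon_hcg	affected	last	860
stop_last_exon_hcg	affected	not_last	122
stop_last_exon_hcg	neutral	last	898
stop_last_exon_hcg	neutral	not_last	85
stop_ir_pmsg	affected	ir	2
stop_ir_pmsg	affected	other	243
stop_ir_pmsg	neutral	ir	18
stop_ir_pmsg	neutral	other	375
domain_body_pmsg	affected	alt_exon	222
domain_body_pmsg	affected	alt_last_exon	168
domain_body_pmsg	affected	alt3	60
domain_body_pmsg	affected	alt5	48
domain_body_pmsg	affected	ir	1
domain_body_pmsg	neutral	alt_exon	305
domain_body_pmsg	neutral	alt_last_exon	215
domain_body_pmsg	neutral	alt3	65
domain_body_pmsg	neutral	alt5	48
domain_body_pmsg	neutral	ir	13
domain_start_pmsg	affected	alt_exon	55
domain_start_pmsg	affected	alt3	26
domain_start_pmsg	affected	alt5	20
domain_start_pmsg	affected	alt_last_exon	7
domain_start_pmsg	affected	ir	1
domain_start_pmsg	neutral	alt_exon	70
domain_start_pmsg	neutral	alt3	25
domain_start_pmsg	neutral	alt5	13
domain_start_pmsg	neutral	alt_last_exon	6
domain_start_pmsg	neutral	ir	2
domain_stop_pmsg	affected	alt_last_exon	140
domain_stop_pmsg	affected	alt_exon	29
domain_stop_pmsg	affected	alt3	15
domain_stop_pmsg	affected	alt5	11
domain_stop_pmsg	affected	ir	0
domain_stop_pmsg	neutral	alt_last_exon	187
domain_stop_pmsg	neutral	alt_exon	40
domain_stop_pmsg	neutral	alt3	19
domain_stop_pmsg	neutral	alt5	17
domain_stop_pmsg	neutral	ir	11
domain_body_hcg	affected	alt_exon	741
domain_body_hcg	affected	alt_last_exon	504
domain_body_hcg	affected	alt3	192
domain_body_hcg	affected	alt5	148
domain_body_hcg	affected	ir	40
domain_body_hcg	neutral	alt_exon	507
domain_body_hcg	neutral	alt_last_exon	415
domain_body_hcg	neutral	alt3	157
domain_body_hcg	neutral	alt5	115
domain_body_hcg	neutral	ir	35
domain_start_hcg	affected	alt_exon	169
domain_start_hcg	affected	alt3	85
domain_start_hcg	affected	alt5	45
domain_start_hcg	affected	alt_last_exon	14
domain_start_hcg	affected	ir	10
domain_start_hcg	neutral	alt_exon	122
domain_start_hcg	neutral	alt3	74
domain_start_hcg	neutral	alt5	31
domain_start_hcg	neutral	alt_last_exon	15
domain_start_hcg	neutral	ir	11
domain_stop_hcg	affected	alt_last_exon	434
domain_stop_hcg	affected	alt_exon	104
domain_stop_hcg	affected	alt5	55
domain_stop_hcg	affected	alt3	40
domain_stop_hcg	affected	ir	30
domain_stop_hcg	neutral	alt_last_exon	372
domain_stop_hcg	neutral	alt_exon	94
domain_stop_hcg	neutral	alt5	58
domain_stop_hcg	neutral	alt3	37
domain_stop_hcg	neutral	ir	23
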