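gene	genome	subtype	divergent	lesion
wtf4	reference	intron1_atg	0	none
wtf13	reference	intron1_atg	0	none
cw4	CBS5557	intron1_atg	0	none
cw18	CBS5557	intron1_atg	0	none
cw23	CBS5557	intron1_atg	0	none
wtf19	reference	exon2_atg	0	none
wtf23	reference	exon2_atg	0	none
cw8a	CBS5557	exon2_atg	0	none
cw9	CBS5557	exon2_atg	0	none
cw21	CBS5557	exon2_atg	0	none
cw22	CBS5557	exon2_atg	0	none
cw27	CBS5557	exon2_atg	0	none
wtf7	reference	none	1	none
wtf11	reference	none	1	none
wtf14	reference	none	1	none
wtf15	reference	none	1	none
cw7	CBS5557	none	1	none
cw11	CBS5557	none	1	none
cw14	CBS5557	none	1	none
cw15	CBS5557	none	1	none
wtf3	reference	none	0	lost_start
cw3	CBS5557	none	0	lost_start
wtf1	reference	none	0	premature_stop
wtf12	reference	none	0	premature_stop
cw12	CBS5557	none	0	premature_stop
cw16	CBS5557	none	0	premature_stop
wtf6	reference	none	0	frameshift_indel
wtf8	reference	none	0	frameshift_indel
wtf22	reference	none	0	frameshift_indel
wtf24	reference	none	0	frameshift_indel
wtf2	reference	none	0	segmental_deletion
wtf17	reference	none	0	segmental_deletion
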