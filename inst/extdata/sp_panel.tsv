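rsid	gene	chromosome	locus_label	major_allele	minor_allele
rs1059047	SFTPA1	10	AA19	T	C
rs1136450	SFTPA1	10	AA50	C	G
rs1136451	SFTPA1	10	AA62	A	G
rs1059057	SFTPA1	10	AA133	A	G
rs4253527	SFTPA1	10	AA219	C	T
rs1059046	SFTPA2	10	AA9	A	C
rs17886395	SFTPA2	10	AA91	C	G
rs1965707	SFTPA2	10	AA140	C	T
rs1965708	SFTPA2	10	AA223	C	A
rs1130866	SFTPB	NA	AA131	T	C
rs4715	SFTPC	8	AA138	C	A
rs1124	SFTPC	8	AA186	G	A
rs721917	SFTPD	10	AA11	A	G
rs2243639	SFTPD	10	AA160	T	C
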