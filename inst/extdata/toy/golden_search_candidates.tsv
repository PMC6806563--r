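variant_id	chrom	pos	ref	alt	edit_class	editor	strand	protospacer_start	protospacer_end	spacer_seq	pam_seq	window_pos	bystanders	preferential
SYN_CR0001	contig1	223	G	A	create_c_to_t	xBE3	-	208	227	TGCCCCCGTACAGCATCCTG	TG	5	4,6,7	FALSE
SYN_CR0001	contig1	223	G	A	create_c_to_t	xBE3	-	210	229	TGTGCCCCCGTACAGCATCC	TG	7	5,6,8	FALSE
SYN_CR0002	contig1	448	C	T	create_c_to_t	BE-PLUS	+	438	457	GAGAATTGAACGCGGATTGT	TGG	11	13	FALSE
SYN_CR0002	contig1	448	C	T	create_c_to_t	hA3A-BE3	+	438	457	GAGAATTGAACGCGGATTGT	TGG	11	13	FALSE
SYN_CR0002	contig1	448	C	T	create_c_to_t	hA3A-eBE	+	438	457	GAGAATTGAACGCGGATTGT	TGG	11	13	FALSE
SYN_CR0002	contig1	448	C	T	create_c_to_t	VQR-BE3	+	441	460	AATTGAACGCGGATTGTTGG	AGA	8	10	FALSE
SYN_CR0002	contig1	448	C	T	create_c_to_t	VQR-BE3	+	439	458	AGAATTGAACGCGGATTGTT	GGA	10		TRUE
SYN_CR0002	contig1	448	C	T	create_c_to_t	EQR-BE3	+	441	460	AATTGAACGCGGATTGTTGG	AGAG	8	10	FALSE
SYN_CR0002	contig1	448	C	T	create_c_to_t	EQR-BE3	+	439	458	AGAATTGAACGCGGATTGTT	GGAG	10		TRUE
SYN_CR0002	contig1	448	C	T	create_c_to_t	xBE3	+	443	462	TTGAACGCGGATTGTTGGAG	AG	6	8	FALSE
SYN_CR0002	contig1	448	C	T	create_c_to_t	xBE3	+	441	460	AATTGAACGCGGATTGTTGG	AG	8		TRUE
SYN_CR0003	contig1	514	G	A	create_c_to_t	BE3	-	501	520	ACGGTTCCAGGGACATCCAC	CGG	7	8	FALSE
SYN_CR0003	contig1	514	G	A	create_c_to_t	eBE-S3	-	501	520	ACGGTTCCAGGGACATCCAC	CGG	7	8	FALSE
SYN_CR0003	contig1	514	G	A	create_c_to_t	BE4max	-	501	520	ACGGTTCCAGGGACATCCAC	CGG	7	8	FALSE
SYN_CR0003	contig1	514	G	A	create_c_to_t	AncBE4max	-	501	520	ACGGTTCCAGGGACATCCAC	CGG	7	8	FALSE
SYN_CR0003	contig1	514	G	A	create_c_to_t	BE-PLUS	-	501	520	ACGGTTCCAGGGACATCCAC	CGG	7	8,14	FALSE
SYN_CR0003	contig1	514	G	A	create_c_to_t	hA3A-BE3	-	501	520	ACGGTTCCAGGGACATCCAC	CGG	7	2,8	FALSE
SYN_CR0003	contig1	514	G	A	create_c_to_t	hA3A-eBE	-	501	520	ACGGTTCCAGGGACATCCAC	CGG	7	2,8	FALSE
SYN_CR0003	contig1	514	G	A	create_c_to_t	hA3A-eBE-Y130F	-	501	520	ACGGTTCCAGGGACATCCAC	CGG	7	8	FALSE
SYN_CR0003	contig1	514	G	A	create_c_to_t	hA3A-eBE-Y132D	-	501	520	ACGGTTCCAGGGACATCCAC	CGG	7	8	FALSE
SYN_CR0003	contig1	514	G	A	create_c_to_t	YE1-BE3	-	501	520	ACGGTTCCAGGGACATCCAC	CGG	7		TRUE
SYN_CR0003	contig1	514	G	A	create_c_to_t	VQR-BE3	-	500	519	CGGTTCCAGGGACATCCACC	GGA	6	7	FALSE
SYN_CR0003	contig1	514	G	A	create_c_to_t	SaBE3	-	502	522	TCACGGTTCCAGGGACATCCA	CCGGAT	9	4,10	FALSE
SYN_CR0003	contig1	514	G	A	create_c_to_t	SaKKH-BE3	-	502	522	TCACGGTTCCAGGGACATCCA	CCGGAT	9	4,10	FALSE
SYN_CR0003	contig1	514	G	A	create_c_to_t	xBE3	-	500	519	CGGTTCCAGGGACATCCACC	GG	6	7	FALSE
SYN_CR0003	contig1	514	G	A	create_c_to_t	xBE3	-	501	520	ACGGTTCCAGGGACATCCAC	CG	7	8	FALSE
SYN_CO0001	contig1	298	A	G	correct_t_to_c	BE3	-	283	302	GCGCCCCCTATCCAAACGGC	GGG	5	4,6,7,8	FALSE
SYN_CO0001	contig1	298	A	G	correct_t_to_c	BE3	-	284	303	AGCGCCCCCTATCCAAACGG	CGG	6	5,7,8	FALSE
SYN_CO0001	contig1	298	A	G	correct_t_to_c	eBE-S3	-	283	302	GCGCCCCCTATCCAAACGGC	GGG	5	4,6,7,8	FALSE
SYN_CO0001	contig1	298	A	G	correct_t_to_c	eBE-S3	-	284	303	AGCGCCCCCTATCCAAACGG	CGG	6	5,7,8	FALSE
SYN_CO0001	contig1	298	A	G	correct_t_to_c	BE4max	-	283	302	GCGCCCCCTATCCAAACGGC	GGG	5	4,6,7,8	FALSE
SYN_CO0001	contig1	298	A	G	correct_t_to_c	BE4max	-	284	303	AGCGCCCCCTATCCAAACGG	CGG	6	5,7,8	FALSE
SYN_CO0001	contig1	298	A	G	correct_t_to_c	AncBE4max	-	283	302	GCGCCCCCTATCCAAACGGC	GGG	5	4,6,7,8	FALSE
SYN_CO0001	contig1	298	A	G	correct_t_to_c	AncBE4max	-	284	303	AGCGCCCCCTATCCAAACGG	CGG	6	5,7,8	FALSE
SYN_CO0001	contig1	298	A	G	correct_t_to_c	BE-PLUS	-	283	302	GCGCCCCCTATCCAAACGGC	GGG	5	4,6,7,8,12,13	FALSE
SYN_CO0001	contig1	298	A	G	correct_t_to_c	BE-PLUS	-	284	303	AGCGCCCCCTATCCAAACGG	CGG	6	5,7,8,9,13,14	FALSE
SYN_CO0001	contig1	298	A	G	correct_t_to_c	BE-PLUS	-	287	306	AGGAGCGCCCCCTATCCAAA	CGG	9	6,8,10,11,12	FALSE
SYN_CO0001	contig1	298	A	G	correct_t_to_c	hA3A-BE3	-	283	302	GCGCCCCCTATCCAAACGGC	GGG	5	2,4,6,7,8,12,13	FALSE
SYN_CO0001	contig1	298	A	G	correct_t_to_c	hA3A-BE3	-	284	303	AGCGCCCCCTATCCAAACGG	CGG	6	3,5,7,8,9,13	FALSE
SYN_CO0001	contig1	298	A	G	correct_t_to_c	hA3A-BE3	-	287	306	AGGAGCGCCCCCTATCCAAA	CGG	9	6,8,10,11,12	FALSE
SYN_CO0001	contig1	298	A	G	correct_t_to_c	hA3A-eBE	-	283	302	GCGCCCCCTATCCAAACGGC	GGG	5	2,4,6,7,8,12,13	FALSE
SYN_CO0001	contig1	298	A	G	correct_t_to_c	hA3A-eBE	-	284	303	AGCGCCCCCTATCCAAACGG	CGG	6	3,5,7,8,9,13	FALSE
SYN_CO0001	contig1	298	A	G	correct_t_to_c	hA3A-eBE	-	287	306	AGGAGCGCCCCCTATCCAAA	CGG	9	6,8,10,11,12	FALSE
SYN_CO0001	contig1	298	A	G	correct_t_to_c	hA3A-eBE-Y130F	-	283	302	GCGCCCCCTATCCAAACGGC	GGG	5	4,6,7,8	FALSE
SYN_CO0001	contig1	298	A	G	correct_t_to_c	hA3A-eBE-Y130F	-	284	303	AGCGCCCCCTATCCAAACGG	CGG	6	3,5,7,8	FALSE
SYN_CO0001	contig1	298	A	G	correct_t_to_c	hA3A-eBE-Y132D	-	283	302	GCGCCCCCTATCCAAACGGC	GGG	5	4,6,7,8	FALSE
SYN_CO0001	contig1	298	A	G	correct_t_to_c	hA3A-eBE-Y132D	-	284	303	AGCGCCCCCTATCCAAACGG	CGG	6	3,5,7,8	FALSE
SYN_CO0001	contig1	298	A	G	correct_t_to_c	YE1-BE3	-	283	302	GCGCCCCCTATCCAAACGGC	GGG	5	6,7	FALSE
SYN_CO0001	contig1	298	A	G	correct_t_to_c	YE1-BE3	-	284	303	AGCGCCCCCTATCCAAACGG	CGG	6	5,7	FALSE
SYN_CO0001	contig1	298	A	G	correct_t_to_c	YE2-BE3	-	283	302	GCGCCCCCTATCCAAACGGC	GGG	5	6	FALSE
SYN_CO0001	contig1	298	A	G	correct_t_to_c	YE2-BE3	-	284	303	AGCGCCCCCTATCCAAACGG	CGG	6	5	FALSE
SYN_CO0001	contig1	298	A	G	correct_t_to_c	YEE-BE3	-	283	302	GCGCCCCCTATCCAAACGGC	GGG	5	6	FALSE
SYN_CO0001	contig1	298	A	G	correct_t_to_c	YEE-BE3	-	284	303	AGCGCCCCCTATCCAAACGG	CGG	6	5	FALSE
SYN_CO0001	contig1	298	A	G	correct_t_to_c	VRER-BE3	-	286	305	GGAGCGCCCCCTATCCAAAC	GGCG	8	5,7,9,10	FALSE
SYN_CO0001	contig1	298	A	G	correct_t_to_c	xBE3	-	282	301	CGCCCCCTATCCAAACGGCG	GG	4	5,6,7	FALSE
SYN_CO0001	contig1	298	A	G	correct_t_to_c	xBE3	-	283	302	GCGCCCCCTATCCAAACGGC	GG	5	4,6,7,8	FALSE
SYN_CO0001	contig1	298	A	G	correct_t_to_c	xBE3	-	284	303	AGCGCCCCCTATCCAAACGG	CG	6	5,7,8	FALSE
SYN_CO0001	contig1	298	A	G	correct_t_to_c	xBE3	-	286	305	GGAGCGCCCCCTATCCAAAC	GG	8	5,7	FALSE
SYN_CO0003	contig1	54	T	C	correct_t_to_c	VQR-BE3	+	47	66	CAACCGTCGATTTTAATAAT	CGA	8	4,5	FALSE
SYN_CO0003	contig1	54	T	C	correct_t_to_c	xBE3	+	47	66	CAACCGTCGATTTTAATAAT	CG	8	4,5	FALSE
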