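variant_id	chrom	pos	edit_class	targetable_editors	preferential_editors	any_targetable	combined_targetable	combined_preferential
SYN_CR0001	contig1	223	create_c_to_t	xBE3		TRUE	TRUE	FALSE
SYN_CR0002	contig1	448	create_c_to_t	BE-PLUS,hA3A-BE3,hA3A-eBE,VQR-BE3,EQR-BE3,xBE3	VQR-BE3,EQR-BE3,xBE3	TRUE	TRUE	TRUE
SYN_CR0003	contig1	514	create_c_to_t	BE3,eBE-S3,BE4max,AncBE4max,BE-PLUS,hA3A-BE3,hA3A-eBE,hA3A-eBE-Y130F,hA3A-eBE-Y132D,YE1-BE3,VQR-BE3,SaBE3,SaKKH-BE3,xBE3	YE1-BE3	TRUE	TRUE	TRUE
SYN_CO0001	contig1	298	correct_t_to_c	BE3,eBE-S3,BE4max,AncBE4max,BE-PLUS,hA3A-BE3,hA3A-eBE,hA3A-eBE-Y130F,hA3A-eBE-Y132D,YE1-BE3,YE2-BE3,YEE-BE3,VRER-BE3,xBE3		TRUE	TRUE	FALSE
SYN_CO0002	contig1	307	correct_t_to_c			FALSE	FALSE	FALSE
SYN_CO0003	contig1	54	correct_t_to_c	VQR-BE3,xBE3		TRUE	TRUE	FALSE
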