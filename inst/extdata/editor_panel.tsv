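name	pam_pattern	pam_side	spacer_length	window_start	window_end	citation
BE3	NGG	three_prime	20	4	8	Komor et al. 2016 Nature
eBE-S3	NGG	three_prime	20	4	8	Wang et al. 2017 Cell Res
BE4max	NGG	three_prime	20	4	8	Koblan et al. 2018 Nat Biotechnol
AncBE4max	NGG	three_prime	20	4	8	Koblan et al. 2018 Nat Biotechnol
BE-PLUS	NGG	three_prime	20	4	14	Jiang et al. 2018 Cell Res
hA3A-BE3	NGG	three_prime	20	2	13	Wang et al. 2018 Nat Biotechnol
hA3A-eBE	NGG	three_prime	20	2	13	Wang et al. 2018 Nat Biotechnol
hA3A-eBE-Y130F	NGG	three_prime	20	3	8	Wang et al. 2018 Nat Biotechnol
hA3A-eBE-Y132D	NGG	three_prime	20	3	8	Wang et al. 2018 Nat Biotechnol
YE1-BE3	NGG	three_prime	20	5	7	Kim et al. 2017 Nat Biotechnol
YE2-BE3	NGG	three_prime	20	5	6	Kim et al. 2017 Nat Biotechnol
YEE-BE3	NGG	three_prime	20	5	6	Kim et al. 2017 Nat Biotechnol
VQR-BE3	NGA	three_prime	20	4	11	Kim et al. 2017 Nat Biotechnol
EQR-BE3	NGAG	three_prime	20	4	11	Kim et al. 2017 Nat Biotechnol
VRER-BE3	NGCG	three_prime	20	3	10	Kim et al. 2017 Nat Biotechnol
SaBE3	NNGRRT	three_prime	21	3	12	Kim et al. 2017 Nat Biotechnol
SaKKH-BE3	NNNRRT	three_prime	21	3	12	Kim et al. 2017 Nat Biotechnol
xBE3	NG	three_prime	20	4	8	Hu et al. 2018 Nature
Target-AID	NGG	three_prime	20	2	4	Nishida et al. 2016 Science
dCpf1-eBE	TTTV	five_prime	23	8	13	Li et al. 2018 Nat Biotechnol
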