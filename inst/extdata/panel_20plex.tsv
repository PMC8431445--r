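step	marker	conjugate	is_negative_control	nc_channel	nc_partner	exclusive_partner
1	FAIM2	FITC	FALSE	SwaRb-FITC	NA	NA
2	CD25	PE	FALSE	NA	NA	NA
3	PD-1	Cy3	FALSE	MsaBiot-Cy3	NA	NA
4	CD29	FITC	FALSE	NA	NA	NA
5	CD24	FITC	FALSE	NA	NA	NA
6	GD2	FITC	FALSE	NA	NA	NA
7	CD3	PE	FALSE	NA	NA	NA
8	CD34	PE	FALSE	NA	NA	NA
9	CD4	PE	FALSE	NA	NA	NA
10	CD20	PE	FALSE	NA	NA	NA
11	CD8	PE	FALSE	NA	NA	NA
12	CD14	PE	FALSE	NA	NA	NA
13	CD44	PE	FALSE	NA	NA	NA
14	CD45	PE	FALSE	NA	NA	NA
15	CD56	PE	FALSE	NA	NA	NA
16	HLA-DR	PE	FALSE	NA	NA	NA
17	HLA-ABC	PE	FALSE	NA	NA	NA
18	B7-H3	PE	FALSE	NA	NA	NA
19	VIM	FITC	FALSE	GtaCh-FITC	NA	NA
20	PI	PI	FALSE	NA	NA	NA
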