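impact_severity	chrom	rs_id	ref	alt	variant_type	functional_impact	gene	af	gnomad_af_all
High	1	rs765451626	CTG	C	Indel	Frameshift	SPEN	0.05592	0.00334
High	1	rs753994746	CAGCTT	C	Indel	Frameshift	ESPN	0.08609	0.00210
High	2	rs527478913	TCGCA	T	Indel	Frameshift	NRP2	0.05556	0.00391
High	3	rs749453662	G	GTT	Indel	Frameshift	ZNF717	0.34545	0.00307
High	11	rs368342230	TG	T	Indel	Frameshift	MUC6	0.05229	0.00000
High	11	rs376177791	G	GT	Indel	Frameshift	MUC6	0.05882	0.00001
High	11	rs780061827	AAT	A	Indel	Frameshift	MUC6	0.27124	0.00000
High	11	rs769713098	G	GCA	Indel	Frameshift	MUC6	0.28431	0.00000
High	19	rs770233746	GGCTT	G	Indel	Frameshift	MUC16	0.29934	0.00000
High	X	rs1325813675	C	CTT	Indel	Splice acceptor	STAG2	0.16807	0.00298
High	X	rs1325813675	C	CTTT	Indel	Splice acceptor	STAG2	0.12832	0.00327
High	X	rs139484145	A	G	SNP	Stop lost	ARSD	0.32895	0.00014
Medium	2	rs143372458	C	T	SNP	Missense	ANKRD23	0.05298	0.00464
Medium	2	rs146511220	C	G	SNP	Missense	ACADL	0.05556	0.00180
Medium	2	rs141080282	G	A	SNP	Missense	LTBP1	0.06250	0.00453
Medium	2	rs142955097	A	G	SNP	Missense	WDR35	0.07843	0.00148
Medium	2	rs55660827	A	G	SNP	Missense	MCM6	0.17974	0.00027
Medium	2	rs1400511133	GGGC	G	Indel	Disruptive inframe deletion	GDF7	0.23077	NA
Medium	4	rs370593066	A	C	SNP	Missense	DCLK2	0.07190	0.00085
Medium	5	rs144066680	A	C	SNP	Missense	GPR151	0.05229	0.00074
Medium	7	rs1351676248	G	T	SNP	Missense	ZSCAN21	0.08553	0.00005
Medium	7	rs75910050	G	A	SNP	Missense	FAM220A	0.05882	0.00094
Medium	11	rs675	T	C	SNP	Missense	APOA4	0.07292	NA
Medium	16	rs149365469	C	T	SNP	Missense	ACD	0.05229	0.00075
Medium	16	rs1799917	A	C	SNP	Missense	GNAO1	0.05556	0.00000
Medium	17	rs140375987	C	T	SNP	Missense	CASC3	0.05882	0.00111
Medium	17	rs758821377	CTGT	C	Indel	Inframe deletion	KDM6B	0.22000	0.00060
Medium	19	rs8107444	A	T	SNP	Missense	ZNF28	0.07813	0.00004
Medium	19	rs1427739410	GGGC	G	Indel	Inframe deletion	BTBD2	0.56818	NA
Medium	20	rs778174473	AGGGCCAGGGCCG	A	Indel	Disruptive inframe deletion	TAF4	0.16667	0.00069
Medium	X	rs78034736	G	T	SNP	Missense	ARSD	0.30921	0.00006
Medium	X	rs73632978	G	A	SNP	Missense	ARSD	0.32026	0.00014
Medium	X	rs67272620	A	T	SNP	Missense	ARSD	0.32353	0.00008
Medium	X	rs67359049	C	T	SNP	Missense	ARSD	0.32353	0.00007
Medium	X	rs73632975	A	T	SNP	Missense	ARSD	0.32353	0.00004
Medium	X	rs73632976	C	T	SNP	Missense	ARSD	0.32353	0.00006
Medium	X	rs370769167	C	T	SNP	Missense	ARSD	0.32680	0.00001
Medium	X	rs115332247	C	A	SNP	Missense	ARSD	0.32680	0.00002
Medium	X	rs73632977	A	T	SNP	Missense	ARSD	0.32680	0.00012
Medium	X	rs73632953	T	C	SNP	Missense	ARSD	0.32895	0.00015
Medium	X	rs73632954	A	G	SNP	Missense	ARSD	0.32895	0.00002
Medium	X	rs143238998	A	C	SNP	Missense	ARSD	0.32895	0.00001
Medium	X	rs150899882	C	A	SNP	Missense	ARSD	0.32895	0.00001
Medium	X	rs113556864	CCCACGCCGG	C	Indel	Disruptive inframe deletion	ARSD	0.32895	0.00001
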