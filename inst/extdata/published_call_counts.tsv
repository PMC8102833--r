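chrom	S015_hg19	S015_majref	S016_hg19	S016_majref	S017_hg19	S017_majref	S018_hg19	S018_majref
chr1	402961	323321	405401	321405	392219	308402	402864	320065
chr2	412000	324350	403261	318001	399028	313695	412509	329532
chr3	333239	260852	343642	277707	325838	259316	346193	280774
chr4	358300	281472	364340	287789	354895	278450	379594	306839
chr5	295294	241912	300598	242585	293180	236954	292577	232489
chr6	286974	232909	300306	242939	280917	225918	289538	233502
chr7	299330	246200	302922	249647	289748	236851	305122	253825
chr8	257291	204661	258232	206143	252234	200180	252235	202257
chr9	237561	198002	235528	193645	228786	187198	243259	202374
chr10	251860	200937	261363	211786	245953	192623	257948	202587
chr11	241812	186658	249891	192248	238592	185276	246142	186443
chr12	231836	180522	241123	193887	225556	175733	233523	183316
chr13	179637	132873	189984	145993	182911	136660	183926	140351
chr14	158917	127299	169846	135970	163253	129121	168611	135653
chr15	148298	117662	159405	130375	149869	118381	149962	119421
chr16	166647	137621	166194	135931	164002	134748	171105	140772
chr17	141183	115298	141107	117433	139916	113209	150595	125584
chr18	141259	108956	139704	108268	137584	105299	144134	111593
chr19	114518	97214	116982	97186	111115	90530	116586	98619
chr20	114760	96896	120655	102872	116883	97734	113170	94965
chr21	93051	78256	95280	80503	88823	73722	91740	76374
chr22	70197	59724	72992	61902	71356	61994	76564	65426
chrX	109924	78173	155003	127580	153143	124112	105958	77079
chrY	23186	22353	21726	21614	18826	18881	23125	23152
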