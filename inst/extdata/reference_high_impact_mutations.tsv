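gene	class	position	genotypes	effect
Solyc01g028980	InDel	39016299	E42	stop_gained
Solyc01g028980	SNP	39016322	E42	stop_gained
Solyc02g049106	SNP	3958278	E8,E17,E36,E42,E53,E76,E107,DOCET	stop_gained
Solyc02g086610	SNP	49909435	E42	splice_acceptor_variant & intron_variant
Solyc02g087620	InDel	50622904	E42	splice_donor_variant & intron_variant
Solyc02g087680	InDel	50664745	E42	frameshift_variant
Solyc02g087690	SNP	50665049	E42	stop_lost & splice_region_variant
Solyc03g070435	InDel	18418311	E8,E53,E76,E107	frameshift_variant
Solyc03g061655	InDel	33847933	E7,E8,E17,E36,E37,E42,E53	frameshift_variant
Solyc03g113310	InDel	64961947	DOCET,JAG8810	frameshift_variant
Solyc03g115910	InDel	66978174	E8,E53	frameshift_variant
Solyc04g050890	SNP	48811041	E42	stop_gained
Solyc05g013120	SNP	6223628	E36,E37	stop_gained
Solyc05g015570	SNP	11438471	DOCET,JAG8810	start_lost
Solyc05g016525	InDel	17404131	DOCET,JAG8810	frameshift_variant
Solyc05g021410	InDel	27336522	E8,E36,E42,E45,E76,E107,DOCET	frameshift_variant
Solyc05g025530	InDel	33154148	DOCET,JAG8810	frameshift_variant
Solyc05g025540	SNP	33160167	DOCET,JAG8810	stop_gained
Solyc05g045790	SNP	58428505	DOCET,JAG8810	splice_donor_variant & intron_variant
Solyc06g005930	InDel	919488	E7,E8,E42,E45,E53,E76,DOCET	frameshift_variant
Solyc06g011663	SNP	11052789	E7,E8,E36,E37,E42,E45,E53,E76	stop_gained
Solyc06g025415	InDel	11106015	E7,E8,E17,E36,E37,E42,E45,E107,DOCET	frameshift_variant
Solyc06g024203	InDel	12303996	E8,E17,E36,E42,E53,E76,E107,JAG8810	frameshift_variant & splice_region_variant
Solyc06g084626	InDel	49741555	E8,E45,E107,JAG8810	frameshift_variant
Solyc06g084626	InDel	49741558	E17,E45,E107,DOCET,JAG8810	frameshift_variant
Solyc07g004993	InDel	4478	E17,E42,E76,DOCET	start_lost
Solyc07g017575	InDel	7582232	E42	stop_gained
Solyc07g021370	SNP	17487354	E42	stop_lost & splice_region_variant
Solyc07g042660	SNP	56308217	E42	splice_acceptor_variant & intron_variant
Solyc07g053565	InDel	62107933	E42	frameshift_variant
Solyc10g054967	SNP	56116455	E17,E42	stop_gained
Solyc11g018853	InDel	9702107	E42,JAG8810	frameshift_variant
Solyc11g020345	SNP	10916212	JAG8810	splice_acceptor_variant & intron_variant
Solyc12g038540	InDel	51497675	E42	frameshift_variant & splice_acceptor_variant & splice_region_variant & intron_variant
Solyc12g038970	InDel	52525425	E8,E36,E37,E45,E53,E76,E107,DOCET,JAG8810	frameshift_variant
Solyc12g044645	InDel	60656260	E42	frameshift_variant
Solyc12g044645	SNP	60656273	E42	stop_lost & splice_region_variant
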