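aa	A	C	D	E	F	G	H	I	K	L	M	N	P	Q	R	S	T	V	W	Y
A	0	1.093	2.9121	3.1585	2.6906	0.9029	2.7391	1.7664	3.2356	1.6587	1.9858	2.284	1.4582	2.5851	3.9367	1.0947	1.2828	1.3177	4.1151	3.2885
C	1.093	0	2.9159	3.0099	1.6261	1.8515	2.2342	0.8519	3.1009	0.6832	0.9411	2.1331	1.4765	2.2534	3.5864	1.3945	1.1176	0.6388	3.1723	2.4174
D	2.9121	2.9159	0	0.453	3.6989	2.651	1.967	3.6597	0.4724	3.4918	2.9197	1.4547	1.7707	1.514	1.3997	1.8986	2.0501	3.518	4.1336	3.2455
E	3.1585	3.0099	0.453	0	3.5985	2.9889	1.8439	3.6956	0.1339	3.5294	2.8742	1.5332	1.9593	1.4547	0.9659	2.152	2.1951	3.6126	3.9	3.0547
F	2.6906	1.6261	3.6989	3.5985	0	3.3639	2.2801	1.291	3.6786	1.2061	0.8645	2.7488	2.5239	2.6064	3.7734	2.7088	2.186	1.7035	1.8291	1.4707
G	0.9029	1.8515	2.651	2.9889	3.3639	0	2.7958	2.6171	3.038	2.4769	2.6044	2.119	1.3862	2.5232	3.8449	0.9923	1.4424	2.1968	4.5356	3.6446
H	2.7391	2.2342	1.967	1.8439	2.2801	2.7958	0	2.7849	1.856	2.5695	1.7718	0.8634	1.4247	0.497	1.9678	1.882	1.4618	2.8284	2.2966	1.3904
I	1.7664	0.8519	3.6597	3.6956	1.291	2.6171	2.7849	0	3.7937	0.2344	1.0791	2.8729	2.2979	2.9134	4.162	2.2463	1.9262	0.4895	3.0885	2.5408
K	3.2356	3.1009	0.4724	0.1339	3.6786	3.038	1.856	3.7937	0	3.6234	2.9602	1.5391	2.0068	1.4609	0.9281	2.2116	2.2555	3.7094	3.9321	3.0897
L	1.6587	0.6832	3.4918	3.5294	1.2061	2.4769	2.5695	0.2344	3.6234	0	0.9007	2.6558	2.0924	2.6996	3.9956	2.0662	1.7173	0.4974	2.9575	2.3665
M	1.9858	0.9411	2.9197	2.8742	0.8645	2.6044	1.7718	1.0791	2.9602	0.9007	0	2.044	1.7232	1.971	3.2074	1.8802	1.3851	1.2946	2.2882	1.5779
N	2.284	2.1331	1.4547	1.5332	2.7488	2.119	0.8634	2.8729	1.5391	2.6558	2.044	0	0.8267	0.453	2.0404	1.2582	1.0737	2.7678	3.1117	2.1778
P	1.4582	1.4765	1.7707	1.9593	2.5239	1.3862	1.4247	2.2979	2.0068	2.0924	1.7232	0.8267	0	1.1653	2.6487	0.4719	0.3787	2.0925	3.359	2.421
Q	2.5851	2.2534	1.514	1.4547	2.6064	2.5232	0.497	2.9134	1.4609	2.6996	1.971	0.453	1.1653	0	1.7629	1.6062	1.3188	2.882	2.7887	1.8739
R	3.9367	3.5864	1.3997	0.9659	3.7734	3.8449	1.9678	4.162	0.9281	3.9956	3.2074	2.0404	2.6487	1.7629	0	2.938	2.8321	4.1796	3.6584	2.9604
S	1.0947	1.3945	1.8986	2.152	2.7088	0.9923	1.882	2.2463	2.2116	2.0662	1.8802	1.2582	0.4719	1.6062	2.938	0	0.5819	1.9563	3.736	2.8107
T	1.2828	1.1176	2.0501	2.1951	2.186	1.4424	1.4618	1.9262	2.2555	1.7173	1.3851	1.0737	0.3787	1.3188	2.8321	0.5819	0	1.7383	3.162	2.2449
V	1.3177	0.6388	3.518	3.6126	1.7035	2.1968	2.8284	0.4895	3.7094	0.4974	1.2946	2.7678	2.0925	2.882	4.1796	1.9563	1.7383	0	3.4373	2.8022
W	4.1151	3.1723	4.1336	3.9	1.8291	4.5356	2.2966	3.0885	3.9321	2.9575	2.2882	3.1117	3.359	2.7887	3.6584	3.736	3.162	3.4373	0	0.9478
Y	3.2885	2.4174	3.2455	3.0547	1.4707	3.6446	1.3904	2.5408	3.0897	2.3665	1.5779	2.1778	2.421	1.8739	2.9604	2.8107	2.2449	2.8022	0.9478	0
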