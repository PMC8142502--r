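aa	A	C	D	E	F	G	H	I	K	L	M	N	P	Q	R	S	T	V	W	Y
A	0	195.004	125.749	106.713	112.581	59.995	85.494	93.662	105.571	96.187	84.44	110.418	26.874	90.761	111.265	99.132	58.023	64.43	147.727	111.588
C	195.004	0	153.574	169.437	204.388	158.232	173.843	197.25	201.579	197.429	195.554	138.766	168.591	154.231	179.535	111.672	148.929	191.233	214.362	193.725
D	125.749	153.574	0	44.605	176.526	93.768	81.238	168.081	101.457	171.757	160.027	23.005	107.91	61.284	95.814	65.471	85.076	152.013	190.552	159.937
E	106.713	169.437	44.605	0	140.212	97.852	40.794	134.162	56.868	138.343	126.085	40.859	93.731	29.274	54.019	79.788	65.501	121.329	152.259	122.777
F	112.581	204.388	176.526	140.212	0	153.126	99.995	21.277	102.141	21.824	28.528	158.112	113.727	115.587	97.033	154.808	102.859	49.935	39.655	21.61
G	59.995	158.232	93.768	97.852	153.126	0	97.533	135.419	126.458	137.692	126.945	79.346	41.629	87.166	125.129	55.267	59.156	108.787	183.79	146.926
H	85.494	173.843	81.238	40.794	99.995	97.533	0	94.338	32.403	98.693	86.344	68.355	76.277	24.084	28.819	88.936	46.753	83.893	114.561	83.328
I	93.662	197.25	168.081	134.162	21.277	135.419	94.338	0	101.612	4.855	10.121	148.914	95.376	108.566	97.587	141.798	89.283	29.609	60.528	33.048
K	105.571	201.579	101.457	56.868	102.141	126.458	32.403	101.612	0	106.336	94.49	93.883	102.714	53.228	26.004	120.533	77.741	96.997	109.435	84.786
L	96.187	197.429	171.757	138.343	21.824	137.692	98.693	4.855	106.336	0	14.303	152.331	97.776	112.441	101.88	144.079	92.354	31.785	60.98	35.677
M	84.44	195.554	160.027	126.085	28.528	126.945	86.344	10.121	94.49	14.303	0	141.153	86.595	100.899	91.638	134.864	81.04	21.522	66.637	35.223
N	110.418	138.766	23.005	40.859	158.112	79.346	68.355	148.914	93.883	152.331	141.153	0	90.157	45.752	85.114	46.24	64.774	132.878	173.782	142.229
P	26.874	168.591	107.91	93.731	113.727	41.629	76.277	95.376	102.714	97.776	86.595	90.157	0	75.136	102.715	73.353	37.564	67.787	146.621	109.616
Q	90.761	154.231	61.284	29.274	115.587	87.166	24.084	108.566	53.228	112.441	100.899	45.752	75.136	0	42.814	68.198	41.105	96.326	130.204	98.783
R	111.265	179.535	95.814	54.019	97.033	125.129	28.819	97.587	26.004	101.88	91.638	85.114	102.715	42.814	0	109.213	70.971	95.797	101.29	77.108
S	99.132	111.672	65.471	79.788	154.808	55.267	88.936	141.798	120.533	144.079	134.864	46.24	73.353	68.198	109.213	0	57.749	123.034	176.578	143.107
T	58.023	148.929	85.076	65.501	102.859	59.156	46.753	89.283	77.741	92.354	81.04	64.774	37.564	41.105	70.971	57.749	0	69.496	128.316	92.248
V	64.43	191.233	152.013	121.329	49.935	108.787	83.893	29.609	96.997	31.785	21.522	132.878	67.787	96.326	95.797	123.034	69.496	0	87.964	54.663
W	147.727	214.362	190.552	152.259	39.655	183.79	114.561	60.528	109.435	60.98	66.637	173.782	146.621	130.204	101.29	176.578	128.316	87.964	0	37.114
Y	111.588	193.725	159.937	122.777	21.61	146.926	83.328	33.048	84.786	35.677	35.223	142.229	109.616	98.783	77.108	143.107	92.248	54.663	37.114	0
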