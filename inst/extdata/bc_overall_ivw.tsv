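Exposure	Outcome	Method	nsnp	b	se	Or	pval	p_fdr
Ratio of conjugated linoleic acid to total fatty acids	Breast cancer	IVW	4	-0.216673334	0.068095147	0.805192956	0.00146302	0.012797408
Ratio of diacylglycerol to triglycerides	Breast cancer	IVW	9	-0.187237837	0.05930465	0.829246488	0.00159281	0.012797408
Conjugated linoleic acid	Breast cancer	IVW	12	-0.13603266	0.041009329	0.872814126	0.000909522	0.0116932
Cholesteryl esters to total lipids ratio in very large HDL	Breast cancer	IVW	43	-0.105953996	0.026041371	0.899466026	4.72803E-05	0.004047276
Total cholesterol to total lipids ratio in very large HDL	Breast cancer	IVW	55	-0.105032845	0.028674002	0.900294952	0.000249279	0.006453565
Triglycerides to total lipids ratio in very large HDL	Breast cancer	IVW	53	-0.101755688	0.030973769	0.9032502	0.001019023	0.0116932
Triglycerides in very large VLDL	Breast cancer	IVW	54	-0.096507778	0.030422678	0.908002835	0.001512724	0.012797408
Concentration of very large VLDL particles	Breast cancer	IVW	53	-0.091780695	0.03025496	0.912305201	0.002416745	0.016561811
Total lipids in very large VLDL	Breast cancer	IVW	54	-0.089023938	0.030548337	0.914823674	0.003566023	0.023080095
Phospholipids in very large VLDL	Breast cancer	IVW	53	-0.08630994	0.030950078	0.917309876	0.005292292	0.028025091
Free cholesterol levels in chylomicrons and extremely large VLDL	Breast cancer	IVW	49	-0.085787698	0.031132418	0.917789059	0.005858916	0.029045264
Triglyceride levels in chylomicrons and extremely large VLDL	Breast cancer	IVW	47	-0.084908368	0.027561538	0.918596453	0.002065262	0.015436768
Concentration of large VLDL particles	Breast cancer	IVW	55	-0.084628182	0.027165058	0.918853867	0.001837378	0.014270301
Total cholesterol in very large VLDL	Breast cancer	IVW	53	-0.083898046	0.030217347	0.919525	0.005494997	0.028451871
Triglycerides in small HDL	Breast cancer	IVW	62	-0.083552301	0.022683977	0.919842977	0.000230218	0.006453565
Free cholesterol in very large VLDL	Breast cancer	IVW	54	-0.08338935	0.032059256	0.919992879	0.00929252	0.040073644
Total lipid levels in chylomicrons and extremely large VLDL	Breast cancer	IVW	51	-0.082681078	0.029249155	0.920644715	0.004701786	0.026719904
Triglycerides in medium VLDL	Breast cancer	IVW	58	-0.082074421	0.023925182	0.9212034	0.000602555	0.009707868
Triglycerides to total lipids ratio in small HDL	Breast cancer	IVW	62	-0.081628257	0.025307021	0.921614499	0.001257448	0.012207727
Ratio of monounsaturated fatty acids to total fatty acids	Breast cancer	IVW	44	-0.080758163	0.026483633	0.922416739	0.002293286	0.016191986
Concentration of chylomicrons and extremely large VLDL particles	Breast cancer	IVW	52	-0.080670967	0.029213107	0.922497174	0.005754272	0.029045264
Triglycerides to total lipids ratio in medium HDL	Breast cancer	IVW	62	-0.080625576	0.027497173	0.922539048	0.003366344	0.022410232
Total lipids in large VLDL	Breast cancer	IVW	54	-0.079991434	0.028174881	0.923124253	0.004524032	0.026352488
Triglycerides in large VLDL	Breast cancer	IVW	58	-0.079123566	0.028307832	0.923925751	0.00518817	0.028025091
Phospholipid levels in chylomicrons and extremely large VLDL	Breast cancer	IVW	47	-0.077694727	0.027318669	0.925246836	0.004454883	0.026352488
Mean diameter of VLDL particles	Breast cancer	IVW	64	-0.075352447	0.026317819	0.927416563	0.004194225	0.026352488
Triglyceride levels in VLDL	Breast cancer	IVW	59	-0.07530692	0.024506989	0.927458787	0.002120071	0.015436768
Concentration of medium VLDL particles	Breast cancer	IVW	59	-0.072784804	0.02584484	0.929800897	0.004859209	0.026957039
Ratio of triglycerides to phosphoglycerides	Breast cancer	IVW	66	-0.071261046	0.026423089	0.931218769	0.006998336	0.03397109
Total lipids in medium VLDL	Breast cancer	IVW	61	-0.069346647	0.026003687	0.933003201	0.00765771	0.034879626
Phospholipids in medium VLDL	Breast cancer	IVW	61	-0.067525853	0.026027636	0.934703556	0.009475878	0.040073644
Phospholipids to total lipids ratio in large HDL	Breast cancer	IVW	41	-0.066370723	0.024806425	0.935783883	0.00746077	0.034879626
Triglycerides in small VLDL	Breast cancer	IVW	64	-0.063442011	0.024506452	0.938528542	0.009631434	0.040073644
Phospholipids in small VLDL	Breast cancer	IVW	74	-0.063301744	0.023786154	0.938660196	0.007784294	0.034879626
Concentration of small VLDL particles	Breast cancer	IVW	72	-0.059178186	0.023596727	0.942538807	0.012145169	0.047963124
Phospholipids to total lipids ratio in very small VLDL	Breast cancer	IVW	50	0.063012037	0.024808333	1.065039659	0.011086691	0.044537914
Total cholesterol to total lipids ratio in medium VLDL	Breast cancer	IVW	42	0.064941761	0.024863786	1.067096876	0.009004019	0.039583706
Cholesterol esters in very large HDL	Breast cancer	IVW	65	0.065036635	0.025363485	1.067198121	0.010341878	0.042274693
Concentration of very large HDL particles	Breast cancer	IVW	84	0.067840501	0.020225461	1.0701946	0.000795911	0.011590456
Total lipids in very large HDL	Breast cancer	IVW	82	0.068105414	0.020574254	1.070478146	0.00093221	0.0116932
Free cholesterol to total lipids ratio in IDL	Breast cancer	IVW	57	0.071785318	0.025269964	1.07442466	0.004500943	0.026352488
Total cholesterol levels in very large HDL	Breast cancer	IVW	71	0.072772387	0.022887702	1.075485714	0.001475085	0.012797408
Apolipoprotein A-I levels	Breast cancer	IVW	64	0.07305185	0.023113164	1.075786315	0.001574356	0.012797408
Total cholesterol to total lipids ratio in medium HDL	Breast cancer	IVW	52	0.073853032	0.027713454	1.076648561	0.007701577	0.034879626
Concentration of large HDL particles	Breast cancer	IVW	75	0.074616292	0.021814187	1.077470637	0.00062497	0.009707868
Phospholipids in very large HDL	Breast cancer	IVW	82	0.076124281	0.021257188	1.079096677	0.000342141	0.007247159
Free cholesterol in large HDL	Breast cancer	IVW	73	0.079035353	0.022043842	1.082242582	0.000336599	0.007247159
Total cholesterol levels in HDL	Breast cancer	IVW	80	0.079740699	0.024443009	1.083006207	0.001105078	0.011703781
Mean diameter of HDL particles	Breast cancer	IVW	84	0.080120491	0.020880579	1.083417602	0.000124505	0.005334934
Free cholesterol in very large HDL	Breast cancer	IVW	77	0.080246838	0.021259802	1.083554497	0.000160277	0.005334934
Total cholesterol in HDL2	Breast cancer	IVW	82	0.081150545	0.023491243	1.084534155	0.00055131	0.009707868
Cholesterol esters in large HDL	Breast cancer	IVW	80	0.082961018	0.020632826	1.086499454	5.79943E-05	0.004047276
Total cholesterol in large HDL	Breast cancer	IVW	79	0.083124214	0.020895689	1.086676781	6.94811E-05	0.004047276
Total lipids in large HDL	Breast cancer	IVW	75	0.083739745	0.02202084	1.08734587	0.000143099	0.005334934
Phospholipids in large HDL	Breast cancer	IVW	69	0.083873975	0.023939707	1.087491834	0.000459099	0.008914181
Total cholesterol to total lipids ratio in large HDL	Breast cancer	IVW	52	0.094939487	0.029356716	1.099592313	0.001220714	0.012207727
Free cholesterol to total lipids ratio in large HDL	Breast cancer	IVW	47	0.101917068	0.031038972	1.107291638	0.001025196	0.0116932
Phospholipids to total lipids ratio in very large HDL	Breast cancer	IVW	49	0.115904545	0.027010679	1.122888682	1.77819E-05	0.004047276
Ratio of omega-6 fatty acids to total fatty acids	Breast cancer	IVW	32	0.123157088	0.03759684	1.131062083	0.001053894	0.0116932
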