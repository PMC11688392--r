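Exposure	Outcome	Method	nsnp	b	se	Or	pval	p_fdr
Apolipoprotein A-I levels	ER- Breast cancer	IVW	65	0.101481929	0.04499003	1.106809917	0.024092327	0.280675611
Citrate levels	ER- Breast cancer	IVW	15	0.230998983	0.064346766	1.259857958	0.000330794	0.053414107
Ratio of conjugated linoleic acid to total fatty acids	ER- Breast cancer	IVW	4	-0.33110009	0.123918613	0.718133287	0.007541959	0.202634062
Ratio of diacylglycerol to triglycerides	ER- Breast cancer	IVW	9	-0.23084858	0.117063758	0.793859663	0.048610729	0.377543329
Ratio of omega-6 fatty acids to total fatty acids	ER- Breast cancer	IVW	32	0.122489849	0.052768668	1.130307646	0.020272765	0.277856133
Glycine levels	ER- Breast cancer	IVW	30	0.064817735	0.025354082	1.066964537	0.010573079	0.202634062
Total cholesterol in HDL2	ER- Breast cancer	IVW	81	0.087638076	0.037473307	1.091592977	0.019351997	0.277856133
Total cholesterol levels in HDL	ER- Breast cancer	IVW	80	0.099890228	0.03583987	1.105049608	0.005317782	0.182845947
Mean diameter of HDL particles	ER- Breast cancer	IVW	85	0.084587951	0.030414876	1.088268554	0.00541688	0.182845947
Isoleucine levels	ER- Breast cancer	IVW	31	-0.176229065	0.070337826	0.838425907	0.012228999	0.202634062
Total cholesterol in large HDL	ER- Breast cancer	IVW	80	0.085429699	0.037365184	1.089184988	0.022234087	0.279150624
Total cholesterol to total lipids ratio in large HDL	ER- Breast cancer	IVW	52	0.125618185	0.038116399	1.133849165	0.000981954	0.076265099
Cholesterol esters in large HDL	ER- Breast cancer	IVW	81	0.085239749	0.037428814	1.088978117	0.022763356	0.279150624
Free cholesterol in large HDL	ER- Breast cancer	IVW	74	0.083014104	0.037797414	1.086557134	0.028071152	0.311456118
Free cholesterol to total lipids ratio in large HDL	ER- Breast cancer	IVW	47	0.102214584	0.047483001	1.107621124	0.031345697	0.317545541
Concentration of large HDL particles	ER- Breast cancer	IVW	75	0.071274635	0.035878429	1.07387611	0.046971231	0.377389547
Phospholipids in large HDL	ER- Breast cancer	IVW	69	0.077904523	0.038389895	1.081019442	0.042427982	0.358232258
Phospholipids to total lipids ratio in large HDL	ER- Breast cancer	IVW	41	-0.104633162	0.037684039	0.900654857	0.005493226	0.182845947
Triglycerides to total lipids ratio in medium HDL	ER- Breast cancer	IVW	63	-0.078636259	0.038478966	0.924376096	0.040991426	0.358232258
Ratio of monounsaturated fatty acids to total fatty acids	ER- Breast cancer	IVW	44	-0.13225597	0.041809065	0.876116707	0.001559741	0.090854936
Ratio of polyunsaturated fatty acids to total fatty acids	ER- Breast cancer	IVW	38	0.108822844	0.051942044	1.11496481	0.036163698	0.35108923
Total cholesterol levels in very large HDL	ER- Breast cancer	IVW	71	0.078902216	0.036296335	1.082098505	0.029717585	0.314736244
Total cholesterol to total lipids ratio in very large HDL	ER- Breast cancer	IVW	55	-0.123318648	0.047490353	0.883981939	0.00941215	0.202634062
Cholesteryl esters to total lipids ratio in very large HDL	ER- Breast cancer	IVW	43	-0.150748731	0.043023074	0.860063779	0.00045849	0.053414107
Free cholesterol in very large HDL	ER- Breast cancer	IVW	77	0.081791125	0.03294661	1.085229109	0.013045111	0.202634062
Total lipids in very large HDL	ER- Breast cancer	IVW	82	0.077309139	0.03009746	1.080376011	0.010210237	0.202634062
Concentration of very large HDL particles	ER- Breast cancer	IVW	84	0.074796148	0.029737804	1.077664444	0.011896916	0.202634062
Phospholipids in very large HDL	ER- Breast cancer	IVW	82	0.081606723	0.031255038	1.085029009	0.009027942	0.202634062
Phospholipids to total lipids ratio in very large HDL	ER- Breast cancer	IVW	48	0.103264604	0.049868605	1.108784759	0.038383683	0.357735923
Triglycerides to total lipids ratio in very large HDL	ER- Breast cancer	IVW	53	-0.093454801	0.046190878	0.910779183	0.04304937	0.358232258
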