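Exposure	Outcome	Method	nsnp	b	se	Or	pval	p_fdr
Conjugated linoleic acid	ER + Breast cancer	IVW	12	-0.152018589	0.051941283	0.858972313	0.00342536	0.021835285
Ratio of diacylglycerol to triglycerides	ER + Breast cancer	IVW	9	-0.182864055	0.066569975	0.832881374	0.006015324	0.032594661
Ratio of omega-6 fatty acids to total fatty acids	ER + Breast cancer	IVW	32	0.136318993	0.041435008	1.146047416	0.001002061	0.013734136
Total cholesterol in HDL2	ER + Breast cancer	IVW	82	0.080548283	0.026760599	1.083881179	0.002612837	0.018704655
Total cholesterol levels in HDL	ER + Breast cancer	IVW	80	0.076018527	0.028118715	1.078982564	0.006861653	0.034468614
Mean diameter of HDL particles	ER + Breast cancer	IVW	84	0.086139223	0.023440504	1.089958065	0.000238033	0.01109236
Free cholesterol to total lipids ratio in IDL	ER + Breast cancer	IVW	57	0.07154162	0.028700792	1.074162857	0.012678641	0.048428251
Total cholesterol in large HDL	ER + Breast cancer	IVW	79	0.09042932	0.024206075	1.094644135	0.000187111	0.01109236
Total cholesterol to total lipids ratio in large HDL	ER + Breast cancer	IVW	52	0.100065484	0.033325784	1.105243291	0.002676449	0.018704655
Cholesterol esters in large HDL	ER + Breast cancer	IVW	80	0.089820853	0.024217597	1.093978283	0.000208155	0.01109236
Cholesteryl esters to total lipids ratio in large HDL	ER + Breast cancer	IVW	42	0.082697537	0.033289251	1.08621322	0.012983871	0.048794226
Free cholesterol in large HDL	ER + Breast cancer	IVW	73	0.084666586	0.025358543	1.088354134	0.000841473	0.013734136
Free cholesterol to total lipids ratio in large HDL	ER + Breast cancer	IVW	47	0.110509811	0.034959687	1.116847306	0.001571939	0.014080872
Total lipids in large HDL	ER + Breast cancer	IVW	75	0.095434541	0.02560649	1.100136806	0.000193798	0.01109236
Concentration of large HDL particles	ER + Breast cancer	IVW	75	0.077750095	0.025409396	1.080852515	0.002214143	0.016641785
Phospholipids in large HDL	ER + Breast cancer	IVW	69	0.092153673	0.027431001	1.096533317	0.000780916	0.013734136
Total Cholesterol in large VLDL	ER + Breast cancer	IVW	60	-0.087587452	0.032784684	0.91613875	0.007549134	0.035896902
Cholesterol esters in large VLDL	ER + Breast cancer	IVW	60	-0.082904306	0.030423844	0.920439223	0.006430577	0.034052827
Total lipids in large VLDL	ER + Breast cancer	IVW	54	-0.091647052	0.031443817	0.912427132	0.003561119	0.021835285
Concentration of large VLDL particles	ER + Breast cancer	IVW	55	-0.096893479	0.030976792	0.907652685	0.001760374	0.014268722
Triglycerides in large VLDL	ER + Breast cancer	IVW	58	-0.088174959	0.032668379	0.91560067	0.006952896	0.034468614
Total cholesterol to total lipids ratio in medium HDL	ER + Breast cancer	IVW	52	0.097533205	0.030717487	1.102448047	0.001497494	0.014080872
Cholesteryl esters to total lipids ratio in medium HDL	ER + Breast cancer	IVW	56	0.081277329	0.029163412	1.084671666	0.005320468	0.03022376
Triglycerides to total lipids ratio in medium HDL	ER + Breast cancer	IVW	62	-0.098000868	0.030974328	0.906648117	0.001556497	0.014080872
Monounsaturated fatty acids (16:1, 18:1) levels	ER + Breast cancer	IVW	63	-0.077206818	0.030538425	0.925698382	0.011465359	0.045278451
Total lipids in medium VLDL	ER + Breast cancer	IVW	61	-0.08447001	0.030286801	0.918999216	0.005287041	0.03022376
Concentration of medium VLDL particles	ER + Breast cancer	IVW	59	-0.086592772	0.03051203	0.917050468	0.004539891	0.027122936
Phospholipids in medium VLDL	ER + Breast cancer	IVW	61	-0.08209343	0.030278922	0.921185888	0.006703206	0.034468614
Triglycerides in medium VLDL	ER + Breast cancer	IVW	59	-0.095842198	0.029013337	0.908607385	0.000955254	0.013734136
Triglycerides in small HDL	ER + Breast cancer	IVW	62	-0.097788898	0.027025362	0.90684032	0.000296416	0.011510825
Triglycerides to total lipids ratio in small HDL	ER + Breast cancer	IVW	62	-0.098269967	0.02925778	0.906404172	0.00078292	0.013734136
Total lipids in small VLDL	ER + Breast cancer	IVW	71	-0.074724735	0.029010997	0.927998897	0.010002634	0.04181601
Concentration of small VLDL particles	ER + Breast cancer	IVW	72	-0.07619846	0.028339749	0.926632289	0.007172041	0.03481428
Phospholipids in small VLDL	ER + Breast cancer	IVW	75	-0.082570028	0.029709211	0.920746957	0.00544806	0.03022376
Triglycerides in small VLDL	ER + Breast cancer	IVW	64	-0.07460138	0.028809352	0.928113377	0.009611966	0.04181601
Ratio of triglycerides to phosphoglycerides	ER + Breast cancer	IVW	67	-0.083195769	0.031863783	0.920170989	0.00902826	0.040453547
Mean diameter of VLDL particles	ER + Breast cancer	IVW	64	-0.086740887	0.029738259	0.91691465	0.003536297	0.021835285
Triglyceride levels in VLDL	ER + Breast cancer	IVW	59	-0.086304883	0.028800235	0.917314515	0.002729435	0.018704655
Total cholesterol to total lipids ratio in very large HDL	ER + Breast cancer	IVW	55	-0.109490345	0.030693707	0.896290818	0.000360827	0.012010388
Cholesteryl esters to total lipids ratio in very large HDL	ER + Breast cancer	IVW	43	-0.102691979	0.029526845	0.90240489	0.000505322	0.013734136
Free cholesterol in very large HDL	ER + Breast cancer	IVW	77	0.077537482	0.026201835	1.080622736	0.003084002	0.020530645
Total lipids in very large HDL	ER + Breast cancer	IVW	82	0.065838065	0.024935073	1.068053748	0.008281314	0.037834238
Concentration of very large HDL particles	ER + Breast cancer	IVW	84	0.065352865	0.024630232	1.067535654	0.007969489	0.037137819
Phospholipids in very large HDL	ER + Breast cancer	IVW	82	0.076484908	0.024187666	1.079485898	0.001566115	0.014080872
Phospholipids to total lipids ratio in very large HDL	ER + Breast cancer	IVW	49	0.132249905	0.029355991	1.141393523	6.64E-06	0.0015462
Triglycerides to total lipids ratio in very large HDL	ER + Breast cancer	IVW	53	-0.125175294	0.036711351	0.88234222	0.000650305	0.013734136
Total cholesterol in very large VLDL	ER + Breast cancer	IVW	53	-0.099959509	0.031419658	0.904874057	0.001465489	0.014080872
Cholesterol esters in very large VLDL	ER + Breast cancer	IVW	50	-0.084979515	0.032980524	0.9185311	0.009976075	0.04181601
Free cholesterol in very large VLDL	ER + Breast cancer	IVW	54	-0.103873465	0.0329738	0.901339341	0.001631689	0.014080872
Total lipids in very large VLDL	ER + Breast cancer	IVW	54	-0.104542657	0.032692882	0.900736374	0.001385191	0.014080872
Concentration of very large VLDL particles	ER + Breast cancer	IVW	53	-0.107293349	0.032395575	0.89826213	0.000926397	0.013734136
Phospholipids in very large VLDL	ER + Breast cancer	IVW	53	-0.102021077	0.033002531	0.903010519	0.00199275	0.015477027
Triglycerides in very large VLDL	ER + Breast cancer	IVW	54	-0.111092154	0.032541852	0.89485628	0.000640579	0.013734136
Total cholesterol levels in chylomicrons and extremely large VLDL	ER + Breast cancer	IVW	56	-0.084373319	0.033698874	0.919088079	0.012288728	0.047721227
Cholesteryl ester levels in chylomicrons and extremely large VLDL	ER + Breast cancer	IVW	60	-0.085110527	0.033274384	0.91841077	0.010532475	0.043053803
Free cholesterol levels in chylomicrons and extremely large VLDL	ER + Breast cancer	IVW	49	-0.100844322	0.032266568	0.904073766	0.001775935	0.014268722
Total lipid levels in chylomicrons and extremely large VLDL	ER + Breast cancer	IVW	51	-0.099274121	0.030419863	0.905494459	0.001100593	0.014080872
Concentration of chylomicrons and extremely large VLDL particles	ER + Breast cancer	IVW	52	-0.097100329	0.030000775	0.907464957	0.001209654	0.014080872
Phospholipid levels in chylomicrons and extremely large VLDL	ER + Breast cancer	IVW	47	-0.091026997	0.028145875	0.912993062	0.001220203	0.014080872
Triglyceride levels in chylomicrons and extremely large VLDL	ER + Breast cancer	IVW	47	-0.100272307	0.029158167	0.904591058	0.000584062	0.013734136
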