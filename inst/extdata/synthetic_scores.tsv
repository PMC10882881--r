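variant	score	label
var_01	0.0602	pathogenic
var_02	-0.5212	benign
var_03	0.9947	pathogenic
var_04	2.7042	pathogenic
var_05	0.5476	benign
var_06	1.8896	pathogenic
var_07	-1.1658	benign
var_08	-1.1793	benign
var_09	0.9292	pathogenic
var_10	1.1515	benign
var_11	0.6275	pathogenic
var_12	1.4953	pathogenic
var_13	1.9954	pathogenic
var_14	0.1257	benign
var_15	-1.2652	benign
var_16	1.6304	pathogenic
var_17	-0.1996	benign
var_18	2.1682	pathogenic
var_19	-0.5617	benign
var_20	-1.1378	benign
var_21	-1.2934	benign
var_22	1.1248	benign
var_23	0.8533	pathogenic
var_24	0.4725	pathogenic
var_25	0.8191	pathogenic
var_26	-1.8304	benign
var_27	2.3955	pathogenic
var_28	1.2609	pathogenic
var_29	-0.2648	benign
var_30	0.9071	benign
var_31	-0.2653	benign
var_32	-0.3286	benign
var_33	-1.3037	benign
var_34	1.6752	pathogenic
var_35	3.1459	pathogenic
var_36	1.3711	pathogenic
var_37	-1.0735	benign
var_38	2.2146	pathogenic
var_39	-0.569	benign
var_40	-0.6188	pathogenic
var_41	2.6313	pathogenic
var_42	0.2918	pathogenic
var_43	1.7959	pathogenic
var_44	0.0367	benign
var_45	1.6962	pathogenic
var_46	-0.843	benign
var_47	-1.2008	benign
var_48	0.5281	benign
var_49	0.4611	pathogenic
var_50	1.5157	pathogenic
var_51	0.5517	benign
var_52	2.4919	pathogenic
var_53	-0.7965	benign
var_54	1.7433	benign
var_55	1.6488	pathogenic
var_56	2.6101	pathogenic
var_57	1.7352	benign
var_58	0.1384	benign
var_59	0.8721	benign
var_60	1.0502	benign
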