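ko	role
K00360	module
K00362	module
K00363	module
K00366	module
K00367	module
K00368	module
K00370	module
K00371	module
K00372	module
K00374	module
K00376	module
K00380	module
K00381	module
K00390	module
K00392	module
K00531	module
K00860	module
K00955	module
K00956	module
K00957	module
K00958	module
K02305	module
K02567	module
K02568	module
K02586	module
K02588	module
K02591	module
K03385	module
K04561	module
K05907	module
K07144	module
K08093	module
K08094	module
K08928	module
K08929	module
K09733	module
K10534	module
K11779	module
K11780	module
K11781	module
K12234	module
K13811	module
K13812	module
K13831	module
K13991	module
K13992	module
K14941	module
K15864	module
K15876	module
K17877	module
K18933	module
K18935	module
K00001	housekeeping
K00002	housekeeping
K00003	housekeeping
K00004	housekeeping
K00005	housekeeping
K00006	housekeeping
K00007	housekeeping
K00008	housekeeping
K00009	housekeeping
K00010	housekeeping
K00011	housekeeping
K00012	housekeeping
K00013	housekeeping
K00014	housekeeping
K00015	housekeeping
K00016	housekeeping
K00017	housekeeping
K00018	housekeeping
K00019	housekeeping
K00020	housekeeping
K00021	housekeeping
K00022	housekeeping
K00023	housekeeping
K00024	housekeeping
K00025	housekeeping
K00026	housekeeping
K00027	housekeeping
K00028	housekeeping
K00029	housekeeping
K00030	housekeeping
K00031	housekeeping
K00032	housekeeping
K00033	housekeeping
K00034	housekeeping
K00035	housekeeping
K00036	housekeeping
K00037	housekeeping
K00038	housekeeping
K00039	housekeeping
K00040	housekeeping
K00041	housekeeping
K00042	housekeeping
K00043	housekeeping
K00044	housekeeping
K00045	housekeeping
K00046	housekeeping
K00047	housekeeping
K00048	housekeeping
K00049	housekeeping
K00050	housekeeping
K00051	housekeeping
K00052	housekeeping
K00053	housekeeping
K00054	housekeeping
K00055	housekeeping
K00056	housekeeping
K00057	housekeeping
K00058	housekeeping
K00059	housekeeping
K00060	housekeeping
K00061	housekeeping
K00062	housekeeping
K00063	housekeeping
K00064	housekeeping
K00065	housekeeping
K00066	housekeeping
K00067	housekeeping
K00068	housekeeping
K00069	housekeeping
K00070	housekeeping
K00071	housekeeping
K00072	housekeeping
K00073	housekeeping
K00074	housekeeping
K00075	housekeeping
K00076	housekeeping
K00077	housekeeping
K00078	housekeeping
K00079	housekeeping
K00080	housekeeping
K00081	housekeeping
K00082	housekeeping
K00083	housekeeping
K00084	housekeeping
K00085	housekeeping
K00086	housekeeping
K00087	housekeeping
K00088	housekeeping
K00089	housekeeping
K00090	housekeeping
K00091	housekeeping
K00092	housekeeping
K00093	housekeeping
K00094	housekeeping
K00095	housekeeping
K00096	housekeeping
K00097	housekeeping
K00098	housekeeping
K00099	housekeeping
K00100	housekeeping
K00101	housekeeping
K00102	housekeeping
K00103	housekeeping
K00104	housekeeping
K00105	housekeeping
K00106	housekeeping
K00107	housekeeping
K00108	housekeeping
K00109	housekeeping
K00110	housekeeping
K00111	housekeeping
K00112	housekeeping
K00113	housekeeping
K00114	housekeeping
K00115	housekeeping
K00116	housekeeping
K00117	housekeeping
K00118	housekeeping
K00119	housekeeping
K00120	housekeeping
K00121	housekeeping
K00122	housekeeping
K00123	housekeeping
K00124	housekeeping
K00125	housekeeping
K00126	housekeeping
K00127	housekeeping
K00128	housekeeping
K00129	housekeeping
K00130	housekeeping
K00131	housekeeping
K00132	housekeeping
K00133	housekeeping
K00134	housekeeping
K00135	housekeeping
K00136	housekeeping
K00137	housekeeping
K00138	housekeeping
K00139	housekeeping
K00140	housekeeping
K00141	housekeeping
K00142	housekeeping
K00143	housekeeping
K00144	housekeeping
K00145	housekeeping
K00146	housekeeping
K00147	housekeeping
K00148	housekeeping
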