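region	lobe	cognitive_network	gyrus_sulcus
G_and_S_frontomargin	frontal	none	mixed
G_and_S_occipital_inf	occipital	VIS	mixed
G_and_S_paracentral	frontal	none	mixed
G_and_S_subcentral	frontal	none	mixed
G_and_S_transv_frontopol	frontal	none	mixed
G_and_S_cingul-Ant	cingulate	SN	mixed
G_and_S_cingul-Mid-Ant	cingulate	SN	mixed
G_and_S_cingul-Mid-Post	cingulate	none	mixed
G_cingul-Post-dorsal	cingulate	DMN	gyrus
G_cingul-Post-ventral	cingulate	DMN	gyrus
G_cuneus	occipital	VIS	gyrus
G_front_inf-Opercular	frontal	none	gyrus
G_front_inf-Orbital	frontal	none	gyrus
G_front_inf-Triangul	frontal	CEN	gyrus
G_front_middle	frontal	CEN	gyrus
G_front_sup	frontal	none	gyrus
G_Ins_lg_and_S_cent_ins	insular	SN	mixed
G_insular_short	insular	SN	gyrus
G_occipital_middle	occipital	VIS	gyrus
G_occipital_sup	occipital	VIS	gyrus
G_oc-temp_lat-fusifor	temporal	none	gyrus
G_oc-temp_med-Lingual	occipital	VIS	gyrus
G_oc-temp_med-Parahip	temporal	DMN	gyrus
G_orbital	frontal	none	gyrus
G_pariet_inf-Angular	parietal	DMN	gyrus
G_pariet_inf-Supramar	parietal	none	gyrus
G_parietal_sup	parietal	CEN	gyrus
G_postcentral	parietal	none	gyrus
G_precentral	frontal	none	gyrus
G_precuneus	parietal	DMN	gyrus
G_rectus	frontal	DMN	gyrus
G_subcallosal	cingulate	none	gyrus
G_temp_sup-G_T_transv	temporal	none	gyrus
G_temp_sup-Lateral	temporal	none	gyrus
G_temp_sup-Plan_polar	temporal	none	gyrus
G_temp_sup-Plan_tempo	temporal	none	gyrus
G_temporal_inf	temporal	none	gyrus
G_temporal_middle	temporal	DMN	gyrus
Lat_Fis-ant-Horizont	frontal	none	sulcus
Lat_Fis-ant-Vertical	frontal	none	sulcus
Lat_Fis-post	temporal	none	sulcus
Pole_occipital	occipital	VIS	gyrus
Pole_temporal	temporal	none	gyrus
S_calcarine	occipital	VIS	sulcus
S_central	frontal	none	sulcus
S_cingul-Marginalis	cingulate	none	sulcus
S_circular_insula_ant	insular	SN	sulcus
S_circular_insula_inf	insular	none	sulcus
S_circular_insula_sup	insular	none	sulcus
S_collat_transv_ant	temporal	none	sulcus
S_collat_transv_post	occipital	none	sulcus
S_front_inf	frontal	CEN	sulcus
S_front_middle	frontal	CEN	sulcus
S_front_sup	frontal	none	sulcus
S_interm_prim-Jensen	parietal	none	sulcus
S_intrapariet_and_P_trans	parietal	CEN	sulcus
S_oc_middle_and_Lunatus	occipital	VIS	sulcus
S_oc_sup_and_transversal	occipital	none	sulcus
S_occipital_ant	occipital	none	sulcus
S_oc-temp_lat	temporal	none	sulcus
S_oc-temp_med_and_Lingual	temporal	none	sulcus
S_orbital_lateral	frontal	none	sulcus
S_orbital_med-olfact	frontal	none	sulcus
S_orbital-H_Shaped	frontal	none	sulcus
S_parieto_occipital	parietal	none	sulcus
S_pericallosal	cingulate	none	sulcus
S_postcentral	parietal	none	sulcus
S_precentral-inf-part	frontal	none	sulcus
S_precentral-sup-part	frontal	none	sulcus
S_suborbital	frontal	DMN	sulcus
S_subparietal	parietal	DMN	sulcus
S_temporal_inf	temporal	none	sulcus
S_temporal_sup	temporal	none	sulcus
S_temporal_transverse	temporal	none	sulcus
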