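panel,variable,eta_intra_pct,eta_inter_pct
myeloid,CD45_Leukocytes,35.15,23.24
myeloid,CD45_Myeloid,54.53,12.70
myeloid,CD172a_Myeloids,42.25,24.21
myeloid,Granulocytes,27.37,32.33
myeloid,Basophils,33.86,19.03
myeloid,Neutrophils,41.48,23.15
myeloid,Eosinophils,18.17,48.83
myeloid,Classical_Monocytes,56.67,17.54
myeloid,Non_classical_monocytes,41.12,34.31
myeloid,Total_Monocytes,28.68,45.25
myeloid,p_DC,64.68,4.88
myeloid,Mature_pDC,51.10,2.94
myeloid,cDC1,16.86,33.11
myeloid,mature_cDC1,16.88,16.88
myeloid,PMN_MDSCs,19.04,13.77
myeloid,M_MDSCs,20.03,14.22
lymphoid,Lymphocytes,37.41,34.31
lymphoid,CD3_Tcells,31.01,37.26
lymphoid,CD4_Tcells,34.89,34.37
lymphoid,CD4_Naive,49.38,5.53
lymphoid,CD4_act_eff,48.64,14.63
lymphoid,CD4_Cmem,36.90,18.04
lymphoid,CD4_Emem,60.87,18.62
lymphoid,CD4_CD44,53.81,13.46
lymphoid,Th1,57.32,11.61
lymphoid,Th1_Eff,32.73,29.35
lymphoid,Th2,65.73,11.52
lymphoid,Th2_Eff,21.74,32.34
lymphoid,Th9,65.74,12.99
lymphoid,Th17,77.49,3.97
lymphoid,Th17_Eff,49.79,14.30
lymphoid,CD4_Treg,52.32,17.97
lymphoid,CD8_T_cells,23.99,48.13
lymphoid,CD8_Naive,45.53,10.11
lymphoid,CD8_act_eff,43.55,17.96
lymphoid,CD8_Cmem,16.57,54.62
lymphoid,CD8_Emem,15.42,32.61
lymphoid,CD8_CD44,29.49,33.52
lymphoid,B_Lymphocytes,20.16,45.08
lymphoid,Plasma_Cells,9.80,76.16
lymphoid,NKT,41.20,14.93
lymphoid,NK,31.41,37.10
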