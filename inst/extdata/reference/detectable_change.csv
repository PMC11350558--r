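panel,variable,mdc_cells,mdc_relative_pct
myeloid,CD45_Leukocytes,363.44,11.68
myeloid,CD45_Myeloid,148.52,17.41
myeloid,CD172a_Myeloids,103.11,14.71
myeloid,Granulocytes,80.04,14.07
myeloid,Basophils,6.043,19.04
myeloid,Neutrophils,39.93,18.51
myeloid,Eosinophils,19.40,19.47
myeloid,Classical_Monocytes,1.06,32.65
myeloid,Non_classical_monocytes,2.89,27.97
myeloid,Total_Monocytes,36.48,21.90
myeloid,p_DC,0.28,38.09
myeloid,Mature_pDC,0.17,38.34
myeloid,cDC1,0.25,29.39
myeloid,mature_cDC1,0.07,30.84
myeloid,PMN_MDSCs,3.59,19.48
myeloid,M_MDSCs,14.68,16.23
lymphoid,Lymphocytes,347.58,16.28
lymphoid,CD3_Tcells,93.22,18.66
lymphoid,CD4_Tcells,40.92,17.72
lymphoid,CD4_Naive,37.00,49.58
lymphoid,CD4_act_eff,34.51,27.13
lymphoid,CD4_Cmem,1.44,33.93
lymphoid,CD4_Emem,4.93,19.85
lymphoid,CD4_CD44,3.90,15.93
lymphoid,Th1,0.25,32.26
lymphoid,Th1_Eff,0.03,37.22
lymphoid,Th2,0.23,54.015
lymphoid,Th2_Eff,0.05,44.73
lymphoid,Th9,2.44,27.66
lymphoid,Th17,0.33,46.06
lymphoid,Th17_Eff,0.07,57.08
lymphoid,CD4_Treg,0.18,32.77
lymphoid,CD8_T_cells,38.82,20.14
lymphoid,CD8_Naive,31.85,37.40
lymphoid,CD8_act_eff,28.65,37.44
lymphoid,CD8_Cmem,5.50,25.24
lymphoid,CD8_Emem,2.85,30.89
lymphoid,CD8_CD44,0.50,29.56
lymphoid,B_Lymphocytes,291.87,20.50
lymphoid,Plasma_Cells,10.11,56.15
lymphoid,NKT,14.13,26.59
lymphoid,NK,13.38,19.05
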