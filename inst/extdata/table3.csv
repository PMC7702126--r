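vector_id,atom_c,atom_h,j_iso_hz,t_aniso_hz,d_exp_hz,d_err_hz,group,use_in_fit,d_calc_mdoc,d_calc_svd_sc,d_calc_svd_mc
C10-H10B,C10,H10B,127.0,141.3,14.3,5.0,CH2_ax,TRUE,12.7,10.4,10.5
C10-H10A,C10,H10A,128.5,151.2,22.7,5.0,CH2_eq,TRUE,21.9,23.7,23.6
C21-H21A,C21,H21A,NA,NA,-4.0,0.3,CH2_eq,TRUE,-4.2,-3.82,-4.0
C21-H21B,C21,H21B,NA,NA,18.2,0.3,CH2_ax,TRUE,18.1,18.8,18.8
C5-H5,C5,H5,NA,NA,24.1,1.3,CH,TRUE,23.4,27.2,27.1
C6-H6,C6,H6,NA,NA,25.8,1.0,CH,TRUE,25.3,25.7,25.6
C22-H22A,C22,H22A,128.0,153.4,25.4,0.3,CH2_ax,TRUE,25.1,24.3,24.1
C22-H22B,C22,H22B,127.8,120.3,-7.5,0.3,CH2_eq,TRUE,-7.5,-11.2,-11.2
C4-H4,C4,H4,NA,NA,-13.8,0.6,CH,TRUE,-13.5,-13.9,-14.0
C9-H9B,C9,H9B,128.7,160.8,32.1,1.5,CH2_ax,TRUE,31.6,30,29.9
C9-H9A,C9,H9A,136.4,123.1,-13.3,0.3,CH2_eq,TRUE,-13.1,-14.4,-14.5
C7-H7B,C7,H7B,128.4,154.8,26.4,5.0,CH2_ax,TRUE,26.8,29.3,29.2
C7-H7A,C7,H7A,137.1,120.5,-16.6,5.0,CH2_eq,TRUE,-13.1,-11.3,-11.4
C23-H23,C23,H23,130.8,157.5,26.7,0.3,CH,TRUE,26.6,26.2,26.2
CH3-28,C28,H28,NA,NA,3.1,0.4,CH3,TRUE,3.0,NA,NA
CH3-26,C26,H26,NA,NA,1.4,0.3,CH3,TRUE,1.3,NA,NA
C2-H2,C2,H2,NA,NA,-25.6,1.8,CH,TRUE,-25.7,-26,-25.9
C3-H3,C3,H3,NA,NA,5.0,0.3,CH,TRUE,5.2,4.2,4.3
C19-H19,C19,H19,NA,NA,-5.2,0.3,CH,TRUE,-5.1,-5.4,-5.1
C17-H17,C17,H17,NA,NA,-19.4,1.0,CH,TRUE,-19.3,-16.6,-17.1
C16-H16,C16,H16,NA,NA,-6.1,1.0,CH,TRUE,-5.9,-5.4,-5.4
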