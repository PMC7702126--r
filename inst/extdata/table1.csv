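coupling,atom_c,atom_h,position,c13_ppm,h1_ppm,j_iso_hz
C9-H9B,C9,H9B,ax,52.9,2.38,128.7
C9-H9A,C9,H9A,eq,52.9,2.93,136.4
C7-H7B,C7,H7B,ax,58.5,2.50,128.4
C7-H7A,C7,H7A,eq,58.5,2.62,137.1
C23-H23,C23,H23,NA,54.6,3.46,130.8
C10-H10B,C10,H10B,ax,21.8,2.53,127.0
C10-H10A,C10,H10A,eq,21.8,2.71,128.5
C22-H22B,C22,H22B,eq,35.0,2.35,127.8
C22-H22A,C22,H22A,ax,35.0,1.74,128.0
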