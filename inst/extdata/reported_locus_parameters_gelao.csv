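locus,n_alleles,Ho,He,p_hwe,GD,PIC,PD_m,PD_f,MEC_Kruger,MEC_Kishida,MEC_Desmarais,MEC_Desmarais_Duo
DXS8378,9,0.6679,0.6149,0.4440,0.6124,0.5502,0.6116,0.7878,0.3528,0.5502,0.5502,0.4034
DXS7423,5,0.5019,0.5433,0.2801,0.5441,0.4548,0.5434,0.7030,0.2607,0.4551,0.4548,0.3162
DXS10148,22,0.8868,0.9049,0.9841,0.9050,0.8959,0.9038,0.9828,0.8053,0.8959,0.8959,0.8185
DXS10159,10,0.7811,0.7827,0.6685,0.7844,0.7510,0.7834,0.9207,0.5802,0.7511,0.7510,0.6214
DXS10134,21,0.8415,0.8531,0.0360,0.8551,0.8376,0.8540,0.9622,0.7093,0.8375,0.8376,0.7339
DXS7424,9,0.7170,0.7295,0.2950,0.7255,0.6811,0.7246,0.8806,0.4952,0.6811,0.6811,0.5411
DXS10164,10,0.6038,0.6134,0.0831,0.5999,0.5595,0.5992,0.7997,0.3766,0.5595,0.5595,0.4110
DXS10162,13,0.7736,0.7627,0.9134,0.7626,0.7251,0.7617,0.9066,0.5471,0.7252,0.7251,0.5907
DXS7132,8,0.7321,0.7622,0.5548,0.7562,0.7166,0.7552,0.9014,0.5347,0.7166,0.7166,0.5805
DXS10079,10,0.7698,0.8109,0.5465,0.8056,0.7775,0.8045,0.9347,0.6184,0.7778,0.7775,0.6542
DXS6789,12,0.8377,0.8121,0.9058,0.8147,0.7890,0.8136,0.9407,0.6353,0.7892,0.7890,0.6689
DXS101,14,0.8076,0.8025,0.3278,0.8103,0.7845,0.8093,0.9388,0.6305,0.7847,0.7845,0.6636
DXS10103,10,0.7547,0.7830,0.0566,0.7738,0.7376,0.7728,0.9132,0.5614,0.7379,0.7376,0.6051
DXS10101,20,0.9019,0.8935,0.3214,0.8920,0.8810,0.8908,0.9783,0.7803,0.8810,0.8810,0.7962
HPRTB,7,0.6943,0.7171,0.5692,0.7220,0.6742,0.7211,0.8754,0.4813,0.6741,0.6742,0.5324
DXS6809,10,0.7698,0.8294,0.0808,0.8320,0.8095,0.8310,0.9499,0.6641,0.8094,0.8095,0.6952
DXS10075,14,0.6830,0.7141,0.0999,0.7071,0.6607,0.7062,0.8682,0.4707,0.6608,0.6607,0.5180
DXS10074,12,0.7434,0.7838,0.5779,0.7835,0.7507,0.7825,0.9209,0.5807,0.7508,0.7507,0.6210
DXS10135,26,0.8981,0.9158,0.1347,0.9177,0.9106,0.9166,0.9871,0.8319,0.9108,0.9106,0.8418
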