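group,n_haplotypes,n_singletons,unique_fraction,HD,MP,PIC,PD_m,PD_f,MEC_Kruger,MEC_Kishida,MEC_Desmarais,MEC_Desmarais_Duo
LG1,179,128,0.7151,0.9970,0.0070,0.9929,0.9930,0.9999,0.9830,0.9900,0.9929,0.9860
LG2,92,49,0.5326,0.9769,0.0271,0.9723,0.9729,0.9986,0.9451,0.9715,0.9723,0.9471
LG3,179,140,0.7821,0.9962,0.0078,0.9921,0.9922,0.9999,0.9805,0.9883,0.9921,0.9845
LG4,54,12,0.2222,0.9713,0.0326,0.9664,0.9674,0.9979,0.9347,0.9667,0.9664,0.9362
LG5,45,11,0.2444,0.9473,0.0565,0.9408,0.9435,0.9941,0.8871,0.9409,0.9408,0.8918
LG6,123,75,0.6098,0.9886,0.0153,0.9844,0.9847,0.9995,0.9677,0.9828,0.9844,0.9697
LG7,36,11,0.3056,0.9344,0.0694,0.9264,0.9306,0.9910,0.8603,0.9264,0.9264,0.8675
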