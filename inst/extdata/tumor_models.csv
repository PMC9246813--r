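species,model_name,tumor_type,tumor_volume_ml,f_mv_pct,f_ecf_pct,ph_ecf,ph_icf,cbf_ml_min_g
rat,C6,rat glioma,0.03,2.25,24.0,7.16,7.28,2.43
rat,BT4C,rat glioma,0.23,1.67,19.0,7.02,7.33,1.14
rat,RG-2,rat glioma,0.075,5.58,13.9,6.87,7.37,0.698
rat,CNS1,rat glioma,0.03,3.92,19.0,7.02,7.33,1.56
rat,R-6,rat rhabdomyosarcoma,0.17,6.52,23.6,6.90,7.37,0.819
rat,9L,rat gliosarcoma,0.20,6.52,23.6,6.90,7.37,0.819
rat,U87-MG,human glioblastoma,NA,5.61,23.3,6.80,NA,0.672
rat,SF188/V+,human glioma,0.12,20.0,20.9,6.86,7.33,16.27
rat,U251,human glioblastoma,NA,4.40,13.7,6.97,NA,NA
human,patient_A,glioblastoma,50,14.9,54.9,6.86,7.31,1.31
human,patient_B,anaplastic astrocytoma,50,15.5,52.6,6.75,7.31,1.17
human,patient_C_D,anaplastic oligodendroglioma,50,16.2,44.3,6.81,7.31,1.17
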