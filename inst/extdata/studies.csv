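species,drug,study,fup,control_type,kpuu_control,tumor_model,kpuu_tumor,ppa_correction
rat,methotrexate,mtx_rg2,0.448,sham,0.114,RG-2,0.105,14.0
rat,methotrexate,mtx_r6,0.448,healthy,0.118,R-6,0.250,36.9
rat,methotrexate,mtx_cns1,0.448,contralateral,0.00527,CNS1,0.123,49.8
rat,temozolomide,tmz_sf188,0.85,contralateral,0.262,SF188/V+,0.227,5.54
rat,ganciclovir,gcv_bt4c,1,contralateral,0.269,BT4C,0.785,4.45
rat,gemcitabine,gem_c6,1,healthy,0.065,C6,0.186,80.1
rat,letrozole,let_c6,0.38,healthy,0.786,C6,1.40,1
rat,cisplatin,cis_9l,1,contralateral,0.049,9L,0.69,1
human,methotrexate,mtx_patient_C,0.677,non_contrast_enhancing,0.0473,patient_A,0.415,892
human,methotrexate,mtx_patient_D,0.677,non_contrast_enhancing,0.139,patient_B,0.451,NA
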