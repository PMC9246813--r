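species,drug,study,structure,cl_cen,q_cen_per,v_cen,v_per,k_el,k_a,lag,omega_cl_pct,omega_v_pct,sigma_prop_pct,sigma_add,fup_scale
rat,methotrexate,mtx_rg2,two_compartment,13.3,10.6,277,661,NA,NA,NA,0,0,8.99,0,1
rat,methotrexate,mtx_r6,two_compartment,20.3,4.23,203,80.9,NA,NA,NA,5.67,0,6.14,54.5,1
rat,methotrexate,mtx_cns1,two_compartment,4.00,1.52,109,163,NA,NA,NA,0,0,10.7,0,1
rat,gemcitabine,gem_c6,two_compartment,1.81,5.75,225,140,NA,NA,NA,0,0,0,39.2,1
rat,letrozole,let_c6,two_compartment,7.6,10,378,80,NA,NA,NA,0,0,1.58,30.6,1
rat,cisplatin,cis_9l,two_compartment,3.11,2.57,91.2,183,NA,NA,NA,0,0,5.84,0,1
rat,temozolomide,tmz_sf188,one_compartment,NA,NA,233,NA,0.0129,NA,NA,6.57,29.3,0,0,0.85
rat,ganciclovir,gcv_bt4c,one_compartment,3.59,NA,75.9,NA,NA,0.00924,19.3,0,0,9.14,0,1
human,methotrexate,mtx_patient_A,two_compartment,163,63.2,20900,10400,NA,NA,NA,0,0,10.7,0,1
human,methotrexate,mtx_patient_B,two_compartment,174,2.78,27700,1670,NA,NA,NA,0,0,3.85,0,1
human,methotrexate,mtx_patient_C,two_compartment,214,15.1,21800,3870,NA,NA,NA,0,0,13.2,0,1
human,methotrexate,mtx_patient_D,two_compartment,160,157,25500,7570,NA,NA,NA,0,0,2.86,45.9,1
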