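species,drug,tumor_model,case_id,f_pore,f_efflux,protocol
rat,methotrexate,RG-2,rat_mtx_rg2,2.66,0.392,separate
rat,methotrexate,R-6,rat_mtx_r6,17.2,0.804,simultaneous
rat,methotrexate,CNS1,rat_mtx_cns1,7.46,0.131,simultaneous
rat,temozolomide,SF188/V+,rat_tmz_sf188,0.172,0.269,simultaneous
rat,ganciclovir,BT4C,rat_gcv_bt4c,2.50,0.101,simultaneous
rat,gemcitabine,C6,rat_gem_c6,21.8,7.81,simultaneous
rat,letrozole,C6,rat_let_c6,49.1,-1.17,simultaneous
rat,cisplatin,9L,rat_cis_9l,8.12,0.0295,simultaneous
human,methotrexate,patient_A,human_mtx,76.0,2.62,simultaneous
human,methotrexate,patient_B,human_mtx,2210,54.7,simultaneous
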