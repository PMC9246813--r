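name,mw,charge_class,pka_acid,pkb_base,logp,fup
methotrexate,454.45,acid,3.41,2.81,-1.85,0.448
temozolomide,194.15,neutral,10.51,-3.6,-1.153,0.85
ganciclovir,255.23,neutral,10.16,1.76,-1.66,1
gemcitabine,263.20,neutral,11.52,3.65,-1.4,1
letrozole,285.30,neutral,NA,2.17,2.5,0.38
cisplatin,300.05,neutral,NA,NA,-2.19,1
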