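trial,source,control,treatment
french,feed_compounds,0.258,0.249
french,roughages,0.043,0.041
french,on_farm_co2,0.001,0.001
french,on_farm_n2o,0.055,0.053
french,on_farm_ch4,0.562,0.542
french,energy,0.007,0.006
french,water,0.003,0.003
french,additive,0,1e-04
french,luc,0.087,0.085
uk,feed_compounds,0.391,0.381
uk,roughages,0.002,0.002
uk,on_farm_co2,0,0
uk,on_farm_n2o,0.041,0.039
uk,on_farm_ch4,0.474,0.457
uk,energy,0.023,0.022
uk,water,0.002,0.002
uk,additive,0,2e-04
uk,luc,0.219,0.213
german,feed_compounds,0.35,0.35
german,roughages,0.02,0.02
german,on_farm_co2,0,0
german,on_farm_n2o,0.05,0.05
german,on_farm_ch4,0.81,0.78
german,energy,0.04,0.04
german,water,0.002,0.002
german,additive,0,1e-04
german,luc,0.03,0.03
french,reported_total,1.016,0.98
uk,reported_total,1.152,1.116
german,reported_total,1.29,1.27
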