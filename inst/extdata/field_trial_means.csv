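group_type,level,trial,applied_n,grain_yield_t_ha,lodging_index,tgw_g,grains_m2,panicles_m2,grains_per_panicle
variety,Balado,IB14,NA,8.86,0.00,43.76,17129,300.2,56.64
variety,Balado,AD14,NA,6.86,0.00,43.71,13301,300.1,43.40
variety,Balado,AD15,NA,4.25,0.00,40.33,9006,400.9,22.05
variety,Gerald,IB14,NA,8.70,9.40,38.94,18943,392.0,48.28
variety,Gerald,AD14,NA,6.26,8.33,36.12,14867,378.5,38.22
variety,Gerald,AD15,NA,3.06,0.00,32.69,8014,432.7,18.38
variety,Mascani,IB14,NA,8.29,0.00,45.85,15308,399.8,37.98
variety,Mascani,AD14,NA,6.52,3.89,45.52,12117,415.2,28.55
variety,Mascani,AD15,NA,4.01,0.00,42.49,7938,502.7,15.45
variety,Tardis,IB14,NA,8.72,10.92,42.57,17564,363.2,47.82
variety,Tardis,AD14,NA,6.52,2.22,41.41,13310,406.3,32.14
variety,Tardis,AD15,NA,4.26,0.00,38.30,9628,482.5,19.57
nitrogen,1,IB14,0,4.90,0.00,41.49,10095,251.8,40.40
nitrogen,1,AD14,0,2.70,0.00,41.10,5580,278.6,20.52
nitrogen,1,AD15,0,2.02,0.00,38.29,4487,321.9,13.92
nitrogen,2,IB14,50,8.05,0.00,44.11,15603,353.7,44.82
nitrogen,2,AD14,50,5.26,0.00,41.92,10724,358.5,31.17
nitrogen,2,AD15,60,2.99,0.00,39.37,6844,425.6,16.27
nitrogen,3,IB14,100,9.26,1.04,42.96,18427,414.6,45.98
nitrogen,3,AD14,100,6.17,0.00,41.38,12773,378.3,34.70
nitrogen,3,AD15,120,4.50,0.00,39.45,9732,482.1,20.57
nitrogen,4,IB14,150,9.74,6.00,42.03,19772,408.1,49.17
nitrogen,4,AD14,150,7.77,1.67,42.01,15860,422.6,38.30
nitrogen,4,AD15,180,4.27,0.00,38.27,9401,480.0,19.92
nitrogen,5,IB14,200,11.25,18.54,43.32,22280,390.8,58.03
nitrogen,5,AD14,200,8.65,3.75,42.84,17302,404.1,43.65
nitrogen,5,AD15,230,4.97,0.00,38.08,11084,514.0,21.74
nitrogen,6,AD14,250,8.90,16.25,41.30,18453,407.9,45.76
nitrogen,6,AD15,280,4.52,0.00,37.27,10335,504.6,20.75
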