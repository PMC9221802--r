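endpoint,variable,pos_yes,pos_n,neg_yes,neg_n,printed_p
cr,sex_male,9,14,28,37,0.490
cr,child_pugh_b,0,14,6,37,0.170
cr,ascites,0,14,8,37,0.088
cr,varices,10,14,29,37,0.715
cr,nonrim_aphe,13,14,36,37,0.478
cr,nonperipheral_washout,11,14,32,37,0.668
cr,enhancing_capsule,6,14,17,37,0.843
cr,threshold_growth,0,14,4,37,0.565
cr,us_visibility,4,14,5,37,0.236
cr,subthreshold_growth,5,14,9,37,0.490
cr,corona_enhancement,1,14,2,37,1.000
cr,fat_sparing,1,14,3,37,1.000
cr,restricted_diffusion,9,14,24,37,1.000
cr,mild_moderate_t2,7,14,20,37,0.796
cr,iron_sparing,0,14,0,37,NA
cr,transitional_hypointensity,9,14,33,37,0.093
cr,hbp_hypointensity,12,14,32,37,1.000
cr,nonenhancing_capsule,0,14,1,37,1.000
cr,nodule_in_nodule,1,14,3,37,1.000
cr,mosaic_architecture,1,14,3,37,1.000
cr,fat_in_mass,2,14,7,37,1.000
cr,blood_products,1,14,0,37,0.275
or,sex_male,20,29,17,22,0.510
or,child_pugh_b,3,29,3,22,1.000
or,ascites,5,29,3,22,1.000
or,varices,22,29,17,22,0.906
or,nonrim_aphe,27,29,22,22,0.500
or,nonperipheral_washout,22,29,21,22,0.117
or,enhancing_capsule,12,29,11,22,0.581
or,threshold_growth,3,29,1,22,0.624
or,us_visibility,5,29,4,22,1.000
or,subthreshold_growth,6,29,8,22,0.214
or,corona_enhancement,2,29,1,22,1.000
or,fat_sparing,3,29,1,22,0.625
or,restricted_diffusion,18,29,15,22,0.651
or,mild_moderate_t2,13,29,14,22,0.183
or,iron_sparing,0,29,0,22,NA
or,transitional_hypointensity,21,29,21,22,0.060
or,hbp_hypointensity,24,29,20,22,0.684
or,nonenhancing_capsule,1,29,0,22,1.000
or,nodule_in_nodule,2,29,2,22,1.000
or,mosaic_architecture,1,29,3,22,0.303
or,fat_in_mass,4,29,5,22,0.474
or,blood_products,1,29,0,22,1.000
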