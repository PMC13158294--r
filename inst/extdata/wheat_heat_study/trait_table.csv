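genotype,treatment,bio_rep,trait,value,unit
Line4,control,1,CAT_activity,8.344291071009483,U/mg protein
Line4,control,1,H2O2,2.1052833277586234,umol/g FW
Line4,control,1,MDA,10.558850777503638,nmol/g FW
Line4,control,1,POX_activity,13.163855994893243,U/mg protein
Line4,control,1,SOD_activity,19.663454079849735,U/mg protein
Line4,control,1,TSS,23.152170496915858,mg/g FW
Line4,control,1,carotenoids,0.5095459095879875,mg/g FW
Line4,control,1,chlorophyll_a,1.7909792147894492,mg/g FW
Line4,control,1,chlorophyll_b,0.6987923263219296,mg/g FW
Line4,control,1,grain_yield,611.1187538369913,g/m2
Line4,control,1,peroxisome_abundance,247.07301684849443,RFU/mg protein
Line4,control,1,proline,2.111056817765739,umol/g FW
Line4,control,2,CAT_activity,8.092586656980457,U/mg protein
Line4,control,2,H2O2,2.343325145084204,umol/g FW
Line4,control,2,MDA,10.02861593751238,nmol/g FW
Line4,control,2,POX_activity,11.859994312588018,U/mg protein
Line4,control,2,SOD_activity,22.615538058140636,U/mg protein
Line4,control,2,TSS,20.69174763831129,mg/g FW
Line4,control,2,carotenoids,0.4939548577444247,mg/g FW
Line4,control,2,chlorophyll_a,1.7651667790212724,mg/g FW
Line4,control,2,chlorophyll_b,0.6745941366787992,mg/g FW
Line4,control,2,grain_yield,620.4741461056971,g/m2
Line4,control,2,peroxisome_abundance,252.94840615937693,RFU/mg protein
Line4,control,2,proline,2.3265693261135705,umol/g FW
Line4,control,3,CAT_activity,8.549666648116927,U/mg protein
Line4,control,3,H2O2,2.4192302050928993,umol/g FW
Line4,control,3,MDA,10.498390199689974,nmol/g FW
Line4,control,3,POX_activity,14.321483153978782,U/mg protein
Line4,control,3,SOD_activity,18.1990188065669,U/mg protein
Line4,control,3,TSS,21.086754770079008,mg/g FW
Line4,control,3,carotenoids,0.5277191684953503,mg/g FW
Line4,control,3,chlorophyll_a,1.8212164637881998,mg/g FW
Line4,control,3,chlorophyll_b,0.6920318492368249,mg/g FW
Line4,control,3,grain_yield,648.4845200761479,g/m2
Line4,control,3,peroxisome_abundance,258.3472378035318,RFU/mg protein
Line4,control,3,proline,2.291034301115015,umol/g FW
Line4,stress,1,CAT_activity,12.210652045093186,U/mg protein
Line4,stress,1,H2O2,4.419351873361357,umol/g FW
Line4,stress,1,MDA,18.27787452548442,nmol/g FW
Line4,stress,1,POX_activity,18.413920800765435,U/mg protein
Line4,stress,1,SOD_activity,26.80697519106692,U/mg protein
Line4,stress,1,TSS,31.10495364859874,mg/g FW
Line4,stress,1,carotenoids,0.451884317101544,mg/g FW
Line4,stress,1,chlorophyll_a,1.654899828789666,mg/g FW
Line4,stress,1,chlorophyll_b,0.6603385539702562,mg/g FW
Line4,stress,1,grain_yield,271.8363970913225,g/m2
Line4,stress,1,peroxisome_abundance,340.92114480159904,RFU/mg protein
Line4,stress,1,proline,3.530195795303128,umol/g FW
Line4,stress,2,CAT_activity,11.81836821453316,U/mg protein
Line4,stress,2,H2O2,4.333991180184646,umol/g FW
Line4,stress,2,MDA,17.143187222397145,nmol/g FW
Line4,stress,2,POX_activity,18.863686281878422,U/mg protein
Line4,stress,2,SOD_activity,24.67055039795005,U/mg protein
Line4,stress,2,TSS,30.138481110499708,mg/g FW
Line4,stress,2,carotenoids,0.47187291157543376,mg/g FW
Line4,stress,2,chlorophyll_a,1.7060094035635391,mg/g FW
Line4,stress,2,chlorophyll_b,0.6165265430576401,mg/g FW
Line4,stress,2,grain_yield,276.4021302387053,g/m2
Line4,stress,2,peroxisome_abundance,367.3825969049304,RFU/mg protein
Line4,stress,2,proline,3.2706459514750565,umol/g FW
Line4,stress,3,CAT_activity,12.470664840701446,U/mg protein
Line4,stress,3,H2O2,4.540301196959961,umol/g FW
Line4,stress,3,MDA,17.831829810069546,nmol/g FW
Line4,stress,3,POX_activity,19.35463970573495,U/mg protein
Line4,stress,3,SOD_activity,25.525780584417298,U/mg protein
Line4,stress,3,TSS,30.432782353982354,mg/g FW
Line4,stress,3,carotenoids,0.4660655308193136,mg/g FW
Line4,stress,3,chlorophyll_a,1.727224159672865,mg/g FW
Line4,stress,3,chlorophyll_b,0.640500617060078,mg/g FW
Line4,stress,3,grain_yield,270.99481071040196,g/m2
Line4,stress,3,peroxisome_abundance,367.6815865515551,RFU/mg protein
Line4,stress,3,proline,3.6470732282956333,umol/g FW
Misr2,control,1,CAT_activity,8.621294980858613,U/mg protein
Misr2,control,1,H2O2,1.8893637915377826,umol/g FW
Misr2,control,1,MDA,9.447708229868017,nmol/g FW
Misr2,control,1,POX_activity,13.382120139778545,U/mg protein
Misr2,control,1,SOD_activity,20.372879973717662,U/mg protein
Misr2,control,1,TSS,23.794800886562324,mg/g FW
Misr2,control,1,carotenoids,0.560354559758684,mg/g FW
Misr2,control,1,chlorophyll_a,1.8580613418387406,mg/g FW
Misr2,control,1,chlorophyll_b,0.7087113105143237,mg/g FW
Misr2,control,1,grain_yield,761.3812551119354,g/m2
Misr2,control,1,peroxisome_abundance,521.9295900855233,RFU/mg protein
Misr2,control,1,proline,2.394299170141097,umol/g FW
Misr2,control,2,CAT_activity,8.11656698036944,U/mg protein
Misr2,control,2,H2O2,1.9575185668389237,umol/g FW
Misr2,control,2,MDA,10.387635513250332,nmol/g FW
Misr2,control,2,POX_activity,14.353691359737692,U/mg protein
Misr2,control,2,SOD_activity,19.95865632370924,U/mg protein
Misr2,control,2,TSS,23.36586141949584,mg/g FW
Misr2,control,2,carotenoids,0.5632752251827936,mg/g FW
Misr2,control,2,chlorophyll_a,1.8569564048908536,mg/g FW
Misr2,control,2,chlorophyll_b,0.7067931216576602,mg/g FW
Misr2,control,2,grain_yield,775.7937000520153,g/m2
Misr2,control,2,peroxisome_abundance,468.34637531889115,RFU/mg protein
Misr2,control,2,proline,2.5371292600442277,umol/g FW
Misr2,control,3,CAT_activity,8.760075655355802,U/mg protein
Misr2,control,3,H2O2,2.05090704023384,umol/g FW
Misr2,control,3,MDA,10.135536866283719,nmol/g FW
Misr2,control,3,POX_activity,14.405313833866915,U/mg protein
Misr2,control,3,SOD_activity,20.771165636862634,U/mg protein
Misr2,control,3,TSS,23.95799469481773,mg/g FW
Misr2,control,3,carotenoids,0.5488853504359521,mg/g FW
Misr2,control,3,chlorophyll_a,1.8609981164281262,mg/g FW
Misr2,control,3,chlorophyll_b,0.7108580769121592,mg/g FW
Misr2,control,3,grain_yield,790.4656191100586,g/m2
Misr2,control,3,peroxisome_abundance,527.4600709885827,RFU/mg protein
Misr2,control,3,proline,2.5687878175641172,umol/g FW
Misr2,stress,1,CAT_activity,14.457515138129063,U/mg protein
Misr2,stress,1,H2O2,3.706961585174368,umol/g FW
Misr2,stress,1,MDA,16.67542771483617,nmol/g FW
Misr2,stress,1,POX_activity,22.040182911740146,U/mg protein
Misr2,stress,1,SOD_activity,33.33920078741808,U/mg protein
Misr2,stress,1,TSS,36.96708208684634,mg/g FW
Misr2,stress,1,carotenoids,0.5010415531250278,mg/g FW
Misr2,stress,1,chlorophyll_a,1.7186765152101486,mg/g FW
Misr2,stress,1,chlorophyll_b,0.6655011352497346,mg/g FW
Misr2,stress,1,grain_yield,368.9857159547854,g/m2
Misr2,stress,1,peroxisome_abundance,825.5018844992381,RFU/mg protein
Misr2,stress,1,proline,5.062923586532909,umol/g FW
Misr2,stress,2,CAT_activity,15.162937261086563,U/mg protein
Misr2,stress,2,H2O2,3.6592023790041273,umol/g FW
Misr2,stress,2,MDA,14.66938300810893,nmol/g FW
Misr2,stress,2,POX_activity,22.394020468472714,U/mg protein
Misr2,stress,2,SOD_activity,31.335940326582673,U/mg protein
Misr2,stress,2,TSS,37.89739351838048,mg/g FW
Misr2,stress,2,carotenoids,0.5008871486704783,mg/g FW
Misr2,stress,2,chlorophyll_a,1.6819374018805358,mg/g FW
Misr2,stress,2,chlorophyll_b,0.6390505806692277,mg/g FW
Misr2,stress,2,grain_yield,349.33212748589267,g/m2
Misr2,stress,2,peroxisome_abundance,794.5239106757293,RFU/mg protein
Misr2,stress,2,proline,5.078887495264252,umol/g FW
Misr2,stress,3,CAT_activity,15.222532627904581,U/mg protein
Misr2,stress,3,H2O2,3.632840405895606,umol/g FW
Misr2,stress,3,MDA,15.610342234110325,nmol/g FW
Misr2,stress,3,POX_activity,22.148397127531975,U/mg protein
Misr2,stress,3,SOD_activity,32.71619606246826,U/mg protein
Misr2,stress,3,TSS,39.94381641153576,mg/g FW
Misr2,stress,3,carotenoids,0.503772574435061,mg/g FW
Misr2,stress,3,chlorophyll_a,1.7707229694568578,mg/g FW
Misr2,stress,3,chlorophyll_b,0.6778714915588506,mg/g FW
Misr2,stress,3,grain_yield,376.17366074890265,g/m2
Misr2,stress,3,peroxisome_abundance,789.9808513515235,RFU/mg protein
Misr2,stress,3,proline,5.157921678882405,umol/g FW
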