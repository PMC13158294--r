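{"seed":1,"design":{"genotypes":{"Misr2":"tolerant","Line4":"susceptible"},"treatments":["control","stress"],"n_bio":3,"n_tech":3,"genes":["TaHSP70","TaHSP90","TaSOD","TaCAT1","TaPEX11.3","TaPEX11.4","TaFIS1A","TaDRP5B"],"reference_gene":"Actin-7","traits":{"grain_yield":"g/m2","H2O2":"umol/g FW","MDA":"nmol/g FW","TSS":"mg/g FW","proline":"umol/g FW","chlorophyll_a":"mg/g FW","chlorophyll_b":"mg/g FW","carotenoids":"mg/g FW","POX_activity":"U/mg protein","SOD_activity":"U/mg protein","CAT_activity":"U/mg protein","peroxisome_abundance":"RFU/mg protein"}},"loadings":{"Misr2":{"genes":["TaHSP70","TaHSP90","TaSOD","TaCAT1","TaPEX11.3","TaPEX11.4","TaFIS1A","TaDRP5B"],"matrix":[[2.16992500144231],[-0.8],[-1],[1.2],[-1.2],[2.4594316186373],[-1],[-1.1]]},"Line4":{"genes":["TaHSP70","TaHSP90","TaSOD","TaCAT1","TaPEX11.3","TaPEX11.4","TaFIS1A","TaDRP5B"],"matrix":[[0.2,0.6529,0.5719,-0.5992,-1.6903],[-0.6,-0.1144,-0.769,-1.6055,0.6302],[0.8,-0.6238,-0.5697,-0.7501,-0.5101],[0.6,-1.285,-1.1792,0.4278,-0.6214],[-0.6,0.8712,-1.4754,-0.702,-0.3246],[0.15,1.402,-0.7219,1.2284,-0.0049],[-0.6,-0.8376,-1.2883,-1.1282,0.043],[0.8,-0.2265,-0.723,-0.9041,-0.1386]]}},"trait_effects":[{"genotype":"Misr2","trait":"grain_yield","control_mean":770.33,"stress_effect":-380.54,"noise_sd":38},{"genotype":"Misr2","trait":"H2O2","control_mean":2.1,"stress_effect":1.6,"noise_sd":0.12},{"genotype":"Misr2","trait":"MDA","control_mean":9.5,"stress_effect":6,"noise_sd":0.5},{"genotype":"Misr2","trait":"TSS","control_mean":24,"stress_effect":14,"noise_sd":1},{"genotype":"Misr2","trait":"proline","control_mean":2.4,"stress_effect":2.6,"noise_sd":0.15},{"genotype":"Misr2","trait":"chlorophyll_a","control_mean":1.85,"stress_effect":-0.12,"noise_sd":0.03},{"genotype":"Misr2","trait":"chlorophyll_b","control_mean":0.72,"stress_effect":-0.05,"noise_sd":0.012},{"genotype":"Misr2","trait":"carotenoids","control_mean":0.55,"stress_effect":-0.04,"noise_sd":0.01},{"genotype":"Misr2","trait":"POX_activity","control_mean":14,"stress_effect":9,"noise_sd":0.7},{"genotype":"Misr2","trait":"SOD_activity","control_mean":21,"stress_effect":12,"noise_sd":1},{"genotype":"Misr2","trait":"CAT_activity","control_mean":8.5,"stress_effect":6.5,"noise_sd":0.45},{"genotype":"Misr2","trait":"peroxisome_abundance","control_mean":520,"stress_effect":300,"noise_sd":25},{"genotype":"Line4","trait":"grain_yield","control_mean":633.45,"stress_effect":-360.2,"noise_sd":8.5},{"genotype":"Line4","trait":"H2O2","control_mean":2.3,"stress_effect":2.1,"noise_sd":0.13},{"genotype":"Line4","trait":"MDA","control_mean":10.2,"stress_effect":7.5,"noise_sd":0.55},{"genotype":"Line4","trait":"TSS","control_mean":22,"stress_effect":8,"noise_sd":1},{"genotype":"Line4","trait":"proline","control_mean":2.2,"stress_effect":1.3,"noise_sd":0.14},{"genotype":"Line4","trait":"chlorophyll_a","control_mean":1.78,"stress_effect":-0.1,"noise_sd":0.03},{"genotype":"Line4","trait":"chlorophyll_b","control_mean":0.69,"stress_effect":-0.05,"noise_sd":0.012},{"genotype":"Line4","trait":"carotenoids","control_mean":0.52,"stress_effect":-0.04,"noise_sd":0.01},{"genotype":"Line4","trait":"POX_activity","control_mean":13,"stress_effect":6,"noise_sd":0.7},{"genotype":"Line4","trait":"SOD_activity","control_mean":20,"stress_effect":5,"noise_sd":1},{"genotype":"Line4","trait":"CAT_activity","control_mean":8,"stress_effect":4,"noise_sd":0.45},{"genotype":"Line4","trait":"peroxisome_abundance","control_mean":240,"stress_effect":130,"noise_sd":18}],"bio_sd":0.1,"tech_sd":0.05,"reference_ct":20,"ct_baseline":{"TaHSP70":24,"TaHSP90":22,"TaSOD":23,"TaCAT1":25,"TaPEX11.3":26,"TaPEX11.4":27,"TaFIS1A":25,"TaDRP5B":26}}
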