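tissue,f_water,f_neutral_lipid,f_phospholipid,f_protein,pH,vol_frac_BW,flow_frac_QC
adipose,0.18,0.785,0.002,0.03,7.1,0.21,0.05
bone,0.44,0.07,0.001,0.2,7.0,0.086,0.05
brain,0.77,0.05,0.05,0.08,7.1,0.02,0.12
gut,0.77,0.05,0.017,0.15,7.0,0.017,0.16
heart,0.76,0.014,0.017,0.17,7.1,0.0047,0.04
kidney,0.79,0.02,0.016,0.16,7.2,0.0044,0.19
liver,0.74,0.035,0.025,0.2,7.0,0.024,0.065
lung,0.79,0.008,0.009,0.16,6.6,0.0076,0.025
muscle,0.76,0.022,0.008,0.2,7.0,0.4,0.17
skin,0.62,0.028,0.011,0.3,7.0,0.037,0.058
spleen,0.78,0.012,0.014,0.18,7.0,0.0026,0.02
red blood cells,0.63,0.0017,0.0029,0.35,7.2,0.033,0
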