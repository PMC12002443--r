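species,BW,QC,Qalv,hct,GFR,liver_mass_frac,hepatocellularity,blood_vol_frac,plasma_pH,body_temperature,source
Human,70,14.0,14.0,0.44,0.265,24.1,110,0.075,7.4,310.15,standard reference physiology compilation
Rat,0.25,13.6,15.0,0.46,0.31,34.0,110,0.074,7.4,311.15,standard reference physiology compilation
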