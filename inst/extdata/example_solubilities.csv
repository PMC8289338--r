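solute,solvent,temperature_C,solubility,units
paracetamol,n-heptane,22,0.005,g_per_100g
acetanilide,n-heptane,22,0.04,g_per_100g
metacetamol,n-heptane,22,0.005,g_per_100g
paracetamol,ethanol,22,0.1544,g_per_g
paracetamol,isopropyl acetate,22,2.73,g_per_100g
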