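solute,cryst_solvent,wash_solvent,wash_fraction,solubility_g_per_100g
paracetamol,2-propanol,n-heptane,0,5.86
paracetamol,2-propanol,n-heptane,0.5,0.171
paracetamol,2-propanol,n-heptane,1,0.005
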