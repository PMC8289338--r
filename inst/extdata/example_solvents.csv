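name,density,viscosity,melting_point,boiling_point,vapor_pressure,enthalpy_vaporization,ich_class,gsk_waste,gsk_environment,gsk_health,gsk_flammability,gsk_reactivity,gsk_life_cycle
ethanol,0.789,0.0012,-114.1,78.4,5870,42.3,3,6,8,8,4,9,8
n-heptane,0.684,0.00041,-90.6,98.4,4730,36.6,3,5,4,6,3,9,7
n-dodecane,0.750,0.00134,-9.6,216.3,18,61.5,,5,4,7,6,9,6
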