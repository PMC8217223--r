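animal,vagus_trunk,pair,pulse_width_ms,threshold_uA,flag
F21-19,ventral,1:2,0.1,400,
F21-19,ventral,3:4,0.1,400,
F21-19,ventral,1:2,0.4,NA,NT
F21-19,ventral,3:4,0.4,NA,NT
F21-19,ventral,1:2,0.5,620,
F21-19,ventral,3:4,0.5,140,
F21-19,ventral,1:2,1.0,460,
F21-19,ventral,3:4,1.0,140,
F22-19,ventral,1:2,0.1,1500,
F22-19,ventral,3:4,0.1,NA,NR
F22-19,ventral,1:2,0.4,NA,NT
F22-19,ventral,3:4,0.4,1500,
F22-19,ventral,1:2,0.5,400,
F22-19,ventral,3:4,0.5,400,
F22-19,ventral,1:2,1.0,400,
F22-19,ventral,3:4,1.0,400,
F19-19,ventral,1:2,0.1,1500,
F19-19,ventral,3:4,0.1,1500,
F19-19,ventral,1:2,0.4,NA,NT
F19-19,ventral,3:4,0.4,NA,NT
F19-19,ventral,1:2,0.5,400,
F19-19,ventral,3:4,0.5,400,
F19-19,ventral,1:2,1.0,220,
F19-19,ventral,3:4,1.0,220,
F25-19,dorsal,1:2,0.1,NA,NR
F25-19,dorsal,3:4,0.1,NA,NR
F25-19,dorsal,1:2,0.4,320,
F25-19,dorsal,3:4,0.4,180,
F25-19,dorsal,1:2,0.5,140,
F25-19,dorsal,3:4,0.5,140,
F25-19,dorsal,1:2,1.0,140,
F25-19,dorsal,3:4,1.0,140,
F26-19,dorsal,1:2,0.1,1500,
F26-19,dorsal,3:4,0.1,1500,
F26-19,dorsal,1:2,0.5,400,
F26-19,dorsal,3:4,0.5,400,
F26-19,dorsal,1:2,1.0,400,
F26-19,dorsal,3:4,1.0,220,
F26-19,dorsal,1:2,0.4,NA,NT
F26-19,dorsal,3:4,0.4,NA,NT
F34-19,dorsal,1:2,0.1,540,
F34-19,dorsal,3:4,0.1,400,
F34-19,dorsal,1:2,0.4,NA,NT
F34-19,dorsal,3:4,0.4,NA,NT
F34-19,dorsal,1:2,0.5,140,
F34-19,dorsal,3:4,0.5,100,
F34-19,dorsal,1:2,1.0,140,
F34-19,dorsal,3:4,1.0,100,
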