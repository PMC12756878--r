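model,species,preparation,n,L_over_P_mean,L_over_P_sd
heart,mouse,imt,3,0.18,0.06
pbmc,human,pce,6,0.08,0.02
platelet,human,pce,6,0.21,0.07
brain,mouse,thom,4,0.19,0.05
hek293t,human,pce,7,0.27,0.06
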