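common_name,aal_stem,bilateral
anterior cingulate cortex,Cingulum_Ant,yes
putamen (nucleus accumbens incorporated),Putamen,yes
inferior orbitofrontal cortex,Frontal_Inf_Orb,yes
medial orbitofrontal cortex,Frontal_Med_Orb,yes
superior medial cortex,Frontal_Sup_Medial,yes
amygdala,Amygdala,yes
superior temporal pole,Temporal_Pole_Sup,yes
middle temporal pole,Temporal_Pole_Mid,yes
precentral cortex,Precentral,yes
supplementary motor area,Supp_Motor_Area,yes
superior occipital cortex,Occipital_Sup,yes
middle occipital cortex,Occipital_Mid,yes
inferior occipital cortex,Occipital_Inf,yes
fusiform gyrus,Fusiform,yes
parietal superior cortex,Parietal_Sup,yes
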