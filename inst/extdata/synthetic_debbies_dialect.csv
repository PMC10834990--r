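RecordID,Class,Order,Family,Species,Common_name,κ,L_b_,L_p_,L_m_,μ_j_,μ_a_,r_B_,R_m_,Contributor,kappa_REF,L_b__REF,L_p__REF,L_m__REF,μ_j__REF,μ_a__REF,r_B__REF,R_m__REF
1,Chondrichthyes,Carcharhiniformes,Synthidae,Carcharhinus fictus,synthetic reef shark,0.8,60,150,280,0.12,0.08,0.08,3,synthetic,assumed,synthetic,synthetic,synthetic,synthetic,synthetic,synthetic,synthetic
2,Reptilia,Testudines,Synthidae,Chelonia ficta,synthetic sea turtle,0.8,5,85,120,0.3,0.05,0.06,90,synthetic,assumed,synthetic,synthetic,synthetic,synthetic,synthetic,synthetic,synthetic
3,Actinopterygii,Perciformes,Synthidae,Epinephelus fictus,synthetic grouper,0.8,0.4,30,100,0.9,0.25,0.2,50000,synthetic,assumed,synthetic,synthetic,synthetic,synthetic,synthetic,synthetic,synthetic
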