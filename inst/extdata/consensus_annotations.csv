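roi_a,hemi_a,roi_b,hemi_b,network,subnetwork,mean_p
Superior Frontal Gyrus,L,Middle Frontal Gyrus,L,Cortical-Limbic,frontal-limbic,9.11e-05
Superior Frontal Gyrus,L,Insula,L,Cortical-Limbic,frontal-limbic,2.05e-04
Superior Orbital Frontal Gyrus,L,Middle Orbital Frontal Gyrus,L,Cortical-Limbic,frontal-limbic,6.49e-05
Superior Orbital Frontal Gyrus,L,Hippocampus,L,Cortical-Limbic,frontal-limbic,8.57e-05
Superior Orbital Frontal Gyrus,L,Putamen,L,Cortical-Limbic,frontal-limbic,3.39e-04
Middle Orbital Frontal Gyrus,L,Inferior Orbital Frontal Gyrus,L,Cortical-Limbic,frontal-limbic,2.16e-04
Middle Orbital Frontal Gyrus,L,Hippocampus,L,Cortical-Limbic,frontal-limbic,1.07e-04
Middle Orbital Frontal Gyrus,L,Putamen,L,Cortical-Limbic,frontal-limbic,2.02e-04
Middle Orbital Frontal Gyrus,L,Pallidum,L,Cortical-Limbic,frontal-limbic,3.57e-04
Inferior Triangular Frontal Gyrus,L,Inferior Orbital Frontal Gyrus,L,Cortical-Limbic,frontal-limbic,2.28e-04
Inferior Orbital Frontal Gyrus,L,Insula,L,Cortical-Limbic,frontal-limbic,6.85e-07
Inferior Orbital Frontal Gyrus,L,Thalamus,L,Cortical-Limbic,frontal-limbic,2.47e-04
Medial Orbital Frontal Gyrus,L,Anterior Cingulate Gyrus,R,Cortical-Limbic,frontal-limbic,3.52e-04
Anterior Cingulate Gyrus,R,Middle Cingulate Gyrus,R,Cortical-Limbic,frontal-limbic,3.92e-05
Supplementary Motor Area,L,Putamen,L,Cortical-Limbic,frontal-limbic,1.51e-04
Supplementary Motor Area,R,Anterior Cingulate Gyrus,R,Cortical-Limbic,frontal-limbic,1.44e-04
Hippocampus,L,Thalamus,L,Cortical-Limbic,frontal-limbic,1.83e-04
Caudate Nucleus,R,Thalamus,R,Cortical-Limbic,frontal-limbic,1.76e-04
Pallidum,L,Thalamus,L,Cortical-Limbic,frontal-limbic,3.46e-04
Insula,R,Superior Parietal Gyrus,R,Cortical-Limbic,parietal-limbic,2.26e-05
Posterior Cingulate Gyrus,R,Superior Parietal Gyrus,R,Cortical-Limbic,parietal-limbic,3.07e-04
Posterior Cingulate Gyrus,R,Precuneus,R,Cortical-Limbic,parietal-limbic,7.61e-05
Superior Parietal Gyrus,R,Putamen,R,Cortical-Limbic,parietal-limbic,1.15e-05
Superior Parietal Gyrus,R,Angular,R,Cortical-Limbic,parietal-limbic,3.97e-04
Precuneus,L,Paracentral Lobule,R,Cortical-Limbic,parietal-limbic,2.12e-05
Fusiform,L,Thalamus,L,Cortical-Limbic,temporal-limbic,4.73e-05
Hippocampus,L,Middle Temporal Gyrus,L,Cortical-Limbic,temporal-limbic,2.15e-04
Hippocampus,L,Inferior Temporal Gyrus,L,Cortical-Limbic,temporal-limbic,1.88e-04
Hippocampus,R,Inferior Temporal Gyrus,R,Cortical-Limbic,temporal-limbic,1.96e-04
Calcarine,R,Inferior Temporal Gyrus,R,Occipital-Temporal,,2.20e-04
Superior Occipital Gyrus,R,Middle Occipital Gyrus,R,Occipital-Temporal,,3.26e-04
Superior Occipital Gyrus,R,Inferior Temporal Gyrus,R,Occipital-Temporal,,5.85e-05
Middle Occipital Gyrus,R,Inferior Temporal Gyrus,R,Occipital-Temporal,,4.16e-04
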