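{
 "aal": {
  "sensorimotor": [
   "Precentral_L",
   "Precentral_R",
   "Postcentral_L",
   "Postcentral_R",
   "Supp_Motor_Area_L",
   "Supp_Motor_Area_R",
   "Paracentral_Lobule_L",
   "Paracentral_Lobule_R",
   "Rolandic_Oper_L",
   "Rolandic_Oper_R",
   "Frontal_Mid_L",
   "Frontal_Mid_R"
  ],
  "default_mode": [
   "Frontal_Sup_L",
   "Frontal_Sup_R",
   "Frontal_Sup_Medial_L",
   "Frontal_Sup_Medial_R",
   "Frontal_Med_Orb_L",
   "Frontal_Med_Orb_R",
   "Frontal_Mid_L",
   "Frontal_Mid_R",
   "Frontal_Inf_Oper_L",
   "Frontal_Inf_Oper_R",
   "Frontal_Inf_Tri_L",
   "Frontal_Inf_Tri_R",
   "Frontal_Inf_Orb_L",
   "Frontal_Inf_Orb_R",
   "Cingulum_Ant_L",
   "Cingulum_Ant_R",
   "Cingulum_Mid_L",
   "Cingulum_Mid_R",
   "Cingulum_Post_L",
   "Cingulum_Post_R",
   "Hippocampus_L",
   "Hippocampus_R",
   "ParaHippocampal_L",
   "ParaHippocampal_R",
   "Angular_L",
   "Angular_R",
   "Precuneus_L",
   "Precuneus_R",
   "Thalamus_L",
   "Thalamus_R",
   "Occipital_Mid_L",
   "Occipital_Mid_R"
  ],
  "visual": [
   "Calcarine_L",
   "Calcarine_R",
   "Cuneus_L",
   "Cuneus_R",
   "Lingual_L",
   "Lingual_R",
   "Occipital_Sup_L",
   "Occipital_Sup_R",
   "Occipital_Mid_L",
   "Occipital_Mid_R",
   "Occipital_Inf_L",
   "Occipital_Inf_R",
   "Fusiform_L",
   "Fusiform_R"
  ],
  "auditory": [
   "Heschl_L",
   "Heschl_R",
   "Temporal_Sup_L",
   "Temporal_Sup_R",
   "Temporal_Mid_L",
   "Temporal_Mid_R"
  ]
 },
 "desikan_killiany": {
  "sensorimotor": [
   "lh-precentral",
   "rh-precentral",
   "lh-postcentral",
   "rh-postcentral",
   "lh-paracentral",
   "rh-paracentral",
   "lh-supramarginal",
   "rh-supramarginal",
   "lh-superiorfrontal",
   "rh-superiorfrontal"
  ],
  "default_mode": [
   "lh-rostralanteriorcingulate",
   "rh-rostralanteriorcingulate",
   "lh-caudalanteriorcingulate",
   "rh-caudalanteriorcingulate",
   "lh-posteriorcingulate",
   "rh-posteriorcingulate",
   "lh-isthmuscingulate",
   "rh-isthmuscingulate",
   "lh-precuneus",
   "rh-precuneus",
   "lh-inferiorparietal",
   "rh-inferiorparietal",
   "lh-parahippocampal",
   "rh-parahippocampal",
   "lh-medialorbitofrontal",
   "rh-medialorbitofrontal",
   "lh-lateralorbitofrontal",
   "rh-lateralorbitofrontal",
   "lh-caudalmiddlefrontal",
   "rh-caudalmiddlefrontal",
   "lh-parstriangularis",
   "rh-parstriangularis",
   "lh-parsorbitalis",
   "rh-parsorbitalis",
   "Left-Thalamus",
   "Right-Thalamus",
   "Left-Hippocampus",
   "Right-Hippocampus"
  ],
  "visual": [
   "lh-lateraloccipital",
   "rh-lateraloccipital",
   "lh-cuneus",
   "rh-cuneus",
   "lh-pericalcarine",
   "rh-pericalcarine",
   "lh-lingual",
   "rh-lingual",
   "lh-fusiform",
   "rh-fusiform"
  ],
  "auditory": [
   "lh-transversetemporal",
   "rh-transversetemporal",
   "lh-superiortemporal",
   "rh-superiortemporal",
   "lh-bankssts",
   "rh-bankssts"
  ]
 }
}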