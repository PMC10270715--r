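label	compartment
lh-bankssts	cerebrum
rh-bankssts	cerebrum
lh-caudalanteriorcingulate	cerebrum
rh-caudalanteriorcingulate	cerebrum
lh-caudalmiddlefrontal	cerebrum
rh-caudalmiddlefrontal	cerebrum
lh-cuneus	cerebrum
rh-cuneus	cerebrum
lh-entorhinal	cerebrum
rh-entorhinal	cerebrum
lh-fusiform	cerebrum
rh-fusiform	cerebrum
lh-inferiorparietal	cerebrum
rh-inferiorparietal	cerebrum
lh-inferiortemporal	cerebrum
rh-inferiortemporal	cerebrum
lh-isthmuscingulate	cerebrum
rh-isthmuscingulate	cerebrum
lh-lateraloccipital	cerebrum
rh-lateraloccipital	cerebrum
lh-lateralorbitofrontal	cerebrum
rh-lateralorbitofrontal	cerebrum
lh-lingual	cerebrum
rh-lingual	cerebrum
lh-medialorbitofrontal	cerebrum
rh-medialorbitofrontal	cerebrum
lh-middletemporal	cerebrum
rh-middletemporal	cerebrum
lh-parahippocampal	cerebrum
rh-parahippocampal	cerebrum
lh-paracentral	cerebrum
rh-paracentral	cerebrum
lh-parsopercularis	cerebrum
rh-parsopercularis	cerebrum
lh-parsorbitalis	cerebrum
rh-parsorbitalis	cerebrum
lh-parstriangularis	cerebrum
rh-parstriangularis	cerebrum
lh-pericalcarine	cerebrum
rh-pericalcarine	cerebrum
lh-postcentral	cerebrum
rh-postcentral	cerebrum
lh-posteriorcingulate	cerebrum
rh-posteriorcingulate	cerebrum
lh-precentral	cerebrum
rh-precentral	cerebrum
lh-precuneus	cerebrum
rh-precuneus	cerebrum
lh-rostralanteriorcingulate	cerebrum
rh-rostralanteriorcingulate	cerebrum
lh-rostralmiddlefrontal	cerebrum
rh-rostralmiddlefrontal	cerebrum
lh-superiorfrontal	cerebrum
rh-superiorfrontal	cerebrum
lh-superiorparietal	cerebrum
rh-superiorparietal	cerebrum
lh-superiortemporal	cerebrum
rh-superiortemporal	cerebrum
lh-supramarginal	cerebrum
rh-supramarginal	cerebrum
lh-frontalpole	cerebrum
rh-frontalpole	cerebrum
lh-temporalpole	cerebrum
rh-temporalpole	cerebrum
lh-transversetemporal	cerebrum
rh-transversetemporal	cerebrum
lh-insula	cerebrum
rh-insula	cerebrum
Left-Thalamus	cerebrum
Right-Thalamus	cerebrum
Left-Caudate	cerebrum
Right-Caudate	cerebrum
Left-Putamen	cerebrum
Right-Putamen	cerebrum
Left-Pallidum	cerebrum
Right-Pallidum	cerebrum
Left-Hippocampus	cerebrum
Right-Hippocampus	cerebrum
Left-Amygdala	cerebrum
Right-Amygdala	cerebrum
Left-Accumbens	cerebrum
Right-Accumbens	cerebrum
Left-Cerebellum-Cortex	cerebellum
Right-Cerebellum-Cortex	cerebellum
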