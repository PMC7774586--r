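roi_id	name	hemisphere	lobe
lh_bankssts	banks of superior temporal sulcus	left	temporal
lh_caudalanteriorcingulate	caudal anterior cingulate	left	frontal
lh_caudalmiddlefrontal	caudal middle frontal	left	frontal
lh_corpuscallosum	corpus callosum	left	frontal
lh_cuneus	cuneus	left	occipital
lh_entorhinal	entorhinal	left	temporal
lh_frontalpole	frontal pole	left	frontal
lh_fusiform	fusiform	left	temporal
lh_inferiorparietal	inferior parietal	left	parietal
lh_inferiortemporal	inferior temporal	left	temporal
lh_insula	insula	left	temporal
lh_isthmuscingulate	isthmus cingulate	left	parietal
lh_lateraloccipital	lateral occipital	left	occipital
lh_lateralorbitofrontal	lateral orbitofrontal	left	frontal
lh_lingual	lingual	left	occipital
lh_medialorbitofrontal	medial orbitofrontal	left	frontal
lh_middletemporal	middle temporal	left	temporal
lh_paracentral	paracentral	left	frontal
lh_parahippocampal	parahippocampal	left	temporal
lh_parsopercularis	pars opercularis	left	frontal
lh_parsorbitalis	pars orbitalis	left	frontal
lh_parstriangularis	pars triangularis	left	frontal
lh_pericalcarine	pericalcarine	left	occipital
lh_postcentral	postcentral	left	parietal
lh_posteriorcingulate	posterior cingulate	left	parietal
lh_precentral	precentral	left	frontal
lh_precuneus	precuneus	left	parietal
lh_rostralanteriorcingulate	rostral anterior cingulate	left	frontal
lh_rostralmiddlefrontal	rostral middle frontal	left	frontal
lh_superiorfrontal	superior frontal	left	frontal
lh_superiorparietal	superior parietal	left	parietal
lh_superiortemporal	superior temporal	left	temporal
lh_supramarginal	supramarginal	left	parietal
lh_temporalpole	temporal pole	left	temporal
lh_transversetemporal	transverse temporal	left	temporal
rh_bankssts	banks of superior temporal sulcus	right	temporal
rh_caudalanteriorcingulate	caudal anterior cingulate	right	frontal
rh_caudalmiddlefrontal	caudal middle frontal	right	frontal
rh_corpuscallosum	corpus callosum	right	frontal
rh_cuneus	cuneus	right	occipital
rh_entorhinal	entorhinal	right	temporal
rh_frontalpole	frontal pole	right	frontal
rh_fusiform	fusiform	right	temporal
rh_inferiorparietal	inferior parietal	right	parietal
rh_inferiortemporal	inferior temporal	right	temporal
rh_insula	insula	right	temporal
rh_isthmuscingulate	isthmus cingulate	right	parietal
rh_lateraloccipital	lateral occipital	right	occipital
rh_lateralorbitofrontal	lateral orbitofrontal	right	frontal
rh_lingual	lingual	right	occipital
rh_medialorbitofrontal	medial orbitofrontal	right	frontal
rh_middletemporal	middle temporal	right	temporal
rh_paracentral	paracentral	right	frontal
rh_parahippocampal	parahippocampal	right	temporal
rh_parsopercularis	pars opercularis	right	frontal
rh_parsorbitalis	pars orbitalis	right	frontal
rh_parstriangularis	pars triangularis	right	frontal
rh_pericalcarine	pericalcarine	right	occipital
rh_postcentral	postcentral	right	parietal
rh_posteriorcingulate	posterior cingulate	right	parietal
rh_precentral	precentral	right	frontal
rh_precuneus	precuneus	right	parietal
rh_rostralanteriorcingulate	rostral anterior cingulate	right	frontal
rh_rostralmiddlefrontal	rostral middle frontal	right	frontal
rh_superiorfrontal	superior frontal	right	frontal
rh_superiorparietal	superior parietal	right	parietal
rh_superiortemporal	superior temporal	right	temporal
rh_supramarginal	supramarginal	right	parietal
rh_temporalpole	temporal pole	right	temporal
rh_transversetemporal	transverse temporal	right	temporal
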