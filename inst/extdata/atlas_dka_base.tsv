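region	lobe	cognitive_network	gyrus_sulcus
bankssts	temporal	none	gyrus
caudalanteriorcingulate	cingulate	SN	gyrus
caudalmiddlefrontal	frontal	CEN	gyrus
cuneus	occipital	VIS	gyrus
entorhinal	temporal	none	gyrus
fusiform	temporal	none	gyrus
inferiorparietal	parietal	DMN	gyrus
inferiortemporal	temporal	none	gyrus
isthmuscingulate	cingulate	DMN	gyrus
lateraloccipital	occipital	VIS	gyrus
lateralorbitofrontal	frontal	none	gyrus
lingual	occipital	VIS	gyrus
medialorbitofrontal	frontal	DMN	gyrus
middletemporal	temporal	DMN	gyrus
parahippocampal	temporal	DMN	gyrus
paracentral	frontal	none	gyrus
parsopercularis	frontal	none	gyrus
parsorbitalis	frontal	none	gyrus
parstriangularis	frontal	CEN	gyrus
pericalcarine	occipital	VIS	gyrus
postcentral	parietal	none	gyrus
posteriorcingulate	cingulate	DMN	gyrus
precentral	frontal	none	gyrus
precuneus	parietal	DMN	gyrus
rostralanteriorcingulate	cingulate	SN	gyrus
rostralmiddlefrontal	frontal	CEN	gyrus
superiorfrontal	frontal	none	gyrus
superiorparietal	parietal	CEN	gyrus
superiortemporal	temporal	none	gyrus
supramarginal	parietal	CEN	gyrus
frontalpole	frontal	none	gyrus
temporalpole	temporal	none	gyrus
transversetemporal	temporal	none	gyrus
insula	insular	SN	gyrus
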