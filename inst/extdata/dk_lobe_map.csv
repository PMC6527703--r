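# Desikan-Killiany region -> lobe assignment, following the FreeSurfer
# lobe definition (mri_annotation2label --lobesStrict), with the cingulate
# divided: anterior cingulate with the frontal lobe, posterior and isthmus
# cingulate with the parietal lobe.  The insula, medial wall ("unknown")
# and corpus callosum are excluded from the four-lobe analysis.
region,lobe
bankssts,temporal
caudalanteriorcingulate,frontal
caudalmiddlefrontal,frontal
corpuscallosum,excluded
cuneus,occipital
entorhinal,temporal
frontalpole,frontal
fusiform,temporal
inferiorparietal,parietal
inferiortemporal,temporal
insula,excluded
isthmuscingulate,parietal
lateraloccipital,occipital
lateralorbitofrontal,frontal
lingual,occipital
medialorbitofrontal,frontal
middletemporal,temporal
paracentral,frontal
parahippocampal,temporal
parsopercularis,frontal
parsorbitalis,frontal
parstriangularis,frontal
pericalcarine,occipital
postcentral,parietal
posteriorcingulate,parietal
precentral,frontal
precuneus,parietal
rostralanteriorcingulate,frontal
rostralmiddlefrontal,frontal
superiorfrontal,frontal
superiorparietal,parietal
superiortemporal,temporal
supramarginal,parietal
temporalpole,temporal
transversetemporal,temporal
unknown,excluded
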