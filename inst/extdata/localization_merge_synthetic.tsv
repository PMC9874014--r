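fine_label	merged_label
Cytosol	Cytosol
Cytoskeleton	Cytosol
Nucleoplasm	Nucleus
Nucleolus	Nucleus
Nuclear membrane	Nucleus
Mitochondria	Mitochondria
Mitochondrial membrane	Mitochondria
Plasma membrane	Plasma membrane
Cell junctions	Plasma membrane
Endoplasmic reticulum	Endoplasmic reticulum
Golgi apparatus	Golgi apparatus
Vesicles	Golgi apparatus
Lysosome	Lysosome
Endosome	Lysosome
Peroxisome	Peroxisome
Secreted	Extracellular
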