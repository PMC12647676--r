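"label","x","y","z"
"Cz",0,0,94.884848
"Fpz",0,90.240853,29.32103
"AFz",0,76.763454,55.771914
"Fz",0,55.771914,76.763454
"FCz",0,29.32103,90.240853
"CPz",0,-29.32103,90.240853
"Pz",0,-55.771914,76.763454
"POz",0,-76.763454,55.771914
"Oz",0,-90.240853,29.32103
"Fp1",-27.885957,85.824151,29.32103
"Fp2",27.885957,85.824151,29.32103
"AF7",-53.042242,73.006383,29.32103
"AF8",53.042242,73.006383,29.32103
"F7",-73.006383,53.042242,29.32103
"F8",73.006383,53.042242,29.32103
"FT7",-85.824151,27.885957,29.32103
"FT8",85.824151,27.885957,29.32103
"T7",-90.240853,0,29.32103
"T8",90.240853,0,29.32103
"TP7",-85.824151,-27.885957,29.32103
"TP8",85.824151,-27.885957,29.32103
"P7",-73.006383,-53.042242,29.32103
"P8",73.006383,-53.042242,29.32103
"PO7",-53.042242,-73.006383,29.32103
"PO8",53.042242,-73.006383,29.32103
"O1",-27.885957,-85.824151,29.32103
"O2",27.885957,-85.824151,29.32103
"T9",-94.884848,0,0
"T10",94.884848,0,0
"TP9",-90.240853,-29.32103,0
"TP10",90.240853,-29.32103,0
"P9",-76.763454,-55.771914,0
"P10",76.763454,-55.771914,0
"PO9",-55.771914,-76.763454,0
"PO10",55.771914,-76.763454,0
"O9",-29.32103,-90.240853,0
"O10",29.32103,-90.240853,0
"C1",-29.32103,0,90.240853
"C2",29.32103,0,90.240853
"C3",-55.771914,0,76.763454
"C4",55.771914,0,76.763454
"C5",-76.763454,0,55.771914
"C6",76.763454,0,55.771914
"F5",-60.793349,54.158687,48.725144
"F3",-43.555042,55.029386,63.858119
"F1",-22.716408,55.582365,73.46904
"F2",22.716408,55.582365,73.46904
"F4",43.555042,55.029386,63.858119
"F6",60.793349,54.158687,48.725144
"FC5",-72.661313,28.466684,53.973288
"FC3",-52.628578,28.925775,73.462008
"FC1",-27.61998,29.219824,85.944592
"FC2",27.61998,29.219824,85.944592
"FC4",52.628578,28.925775,73.462008
"FC6",72.661313,28.466684,53.973288
"CP5",-72.661313,-28.466684,53.973288
"CP3",-52.628578,-28.925775,73.462008
"CP1",-27.61998,-29.219824,85.944592
"CP2",27.61998,-29.219824,85.944592
"CP4",52.628578,-28.925775,73.462008
"CP6",72.661313,-28.466684,53.973288
"P5",-60.793349,-54.158687,48.725144
"P3",-43.555042,-55.029386,63.858119
"P1",-22.716408,-55.582365,73.46904
"P2",22.716408,-55.582365,73.46904
"P4",43.555042,-55.029386,63.858119
"P6",60.793349,-54.158687,48.725144
"AF3",-29.695304,75.771152,48.785815
"AF4",29.695304,75.771152,48.785815
"PO3",-29.695304,-75.771152,48.785815
"PO4",29.695304,-75.771152,48.785815
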