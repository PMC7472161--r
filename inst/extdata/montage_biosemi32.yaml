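# Default 32-channel symmetric montage (Biosemi-style 10-20 layout):
# 4 midline channels and 14 interhemispheric pairs.
midline: [Fz, Cz, Pz, Oz]
pairs:
  - [Fp1, Fp2]
  - [AF3, AF4]
  - [F7, F8]
  - [F3, F4]
  - [FC5, FC6]
  - [FC1, FC2]
  - [T7, T8]
  - [C3, C4]
  - [CP5, CP6]
  - [CP1, CP2]
  - [P7, P8]
  - [P3, P4]
  - [PO3, PO4]
  - [O1, O2]
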