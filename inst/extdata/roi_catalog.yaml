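# Cortical regions of interest and their constituent atlas scouts
# (USCBrain atlas naming). Composite regions (anterior insula,
# orbitofrontal cortex) combine several scouts; their representative time
# series is the first principal component across scouts.
anterior_insula_L:
  - "Insula—anterior L"
  - "Pars Opercularis—Inferior L"
  - "Pars Opercularis—Superior L"
  - "Pars Triangularis—Middle L"
  - "Pars Triangularis—Posterior L"
anterior_insula_R:
  - "Insula—anterior R"
  - "Pars Opercularis—Inferior R"
  - "Pars Opercularis—Superior R"
  - "Pars Triangularis—Middle R"
  - "Pars Triangularis—Posterior R"
ACC_L:
  - "Cingulate Gyrus—Anterior L"
ACC_R:
  - "Cingulate Gyrus—Anterior R"
PCC_L:
  - "Cingulate Gyrus—Posterior L"
PCC_R:
  - "Cingulate Gyrus—Posterior R"
precuneus_L:
  - "Precuneus—Inferior L"
precuneus_R:
  - "Precuneus—Inferior R"
OFC_L:
  - "Anterior Orbito-frontal Gyrus L"
  - "Gyrus Rectus L"
  - "Middle Orbito-frontal Gyrus L"
OFC_R:
  - "Anterior Orbito-frontal Gyrus R"
  - "Gyrus Rectus R"
  - "Middle Orbito-frontal Gyrus R"
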