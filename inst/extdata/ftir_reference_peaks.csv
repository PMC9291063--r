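class,peaks
PP,2915;1455;1377;997;982
LDPE,2915;2845;1462;717
HDPE,2915;2845;1462;717
PS,3024;2847;1492;1451;694
PET,1713;1241;1094;720
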