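>P1;t80
structureX:t80.pdb:1:A:80:A::::
ACDEFGHIKLMNPQRSTVWYACDEFGHIKLMNPQRSTVWYACDEFGHIKLMNPQRSTVWYACDEFGHIKLMNPQR
STVWY*
>P1;s80
sequence:s80::::::::
ACDEFGHIKLMNPQRSTVWYACDEFGHIKLMNPQRSTVWYACDEFGHIKLMNPQRSTVWYACDEFGHIKLMNPQR
STVWY*
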