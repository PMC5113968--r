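>P1;tmpl3
structureX:tmpl3.pdb:1:A:102:A::::
ACDEFGHIKL..*
>P1;tgt3
sequence:tgt3::::::::
ACDEFGHIKL..*
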