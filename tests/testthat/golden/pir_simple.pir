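>P1;tmpl1
structureX:tmpl1.pdb:1:A:6:A::::
MKLVRT*
>P1;tgt1
sequence:tgt1::::::::
MKLVRT*
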