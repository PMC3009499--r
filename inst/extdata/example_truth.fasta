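>prot01
iiiiiiiiiiMMMMMMMMMMMMMMMMMMMMoooMMMMMMMMMMMMMMMMMMMMMMiiiiiiiiiiiiiiiiiiiiiiiii
iiiiiiiiiiiiiiiiiMMMMMMMMMMMMMMMMMoooMMMMMMMMMMMMMMMMMMMMMMMMiiiiiiiiiiiiiiiiiii
iiiiiiMMMMMMMMMoooooooooooooooooooMMMMMMMMiMMMMMMMMMMMMMMMMMMMMMMMMMMMMMMMoooooo
ooooooooooooooooooooooooooMMMMMMMMMMMMMMMMMiiiiiiiiiiiiiiiii
>prot02
ooooooooooooooooooMMMMMMMiiiiiiiiiiiiiiiiiiiMMMMMMMMMMMMMMMMMMMMMMMMMMMMMMMMMMMM
MMMMMMMMMMMMMMMMMMMMMoooooooooooooooooooooooooooooooMMMMMMMMMMMMMMMMMMMMMMMMMiii
iiiiiiiiiiiiiiiiiiiiiiiiiiiiiiiiiiiiiiiiiiiiMMMMMMMMMooooooooooooooooooooooooMMM
MMMMMMMMMMMMMMMMMMMMMMMMMMMMMMMMMMMiiiiiiiiiiiiiiiiiiiiiiiii
>prot03
ooooooooMMMMMMMMMMMiiiiiiiiiiiiiiiiiMMMMMMMMMMMMMMMMMMMoooooooMMMMMMMiiiiiiiiiii
iiiiiMMMMMMMMMMMMMooooooooooooooMMMMMMMMMMiiiiiiiiiiiiiiiiiiiiiiiiiiiiiiiiiiiiii
iiMMMMMMMMMMMMMMMoMMMMMMMMMMMMMMMMMMMMMMMMMMMMMMMMMMMMMMMMMMMMMMMiiiiiiiiiiiiiii
iiiiiiiiiiiiiiiiiiiiiiiiiiiiMMMMMMMMMMMMMMMMMMMMMMMMMMMMMMMM
>prot04
iiiiiiiiiiiMMMMMMMMMMMMoooooooooooooMMMMMMMMMMMiiiiiiiiiiiiiiiMMMMMMMMMMMMMMMMMM
MMMMMMMMMMMMMMMMMMMMMoooMMMMMMMMMMMMMMiiiiiiiiiiiiiMMMMMMMMMMMMMMMMMMooooooooooo
oMMMMMMMMMMiiiiiiiiiiiiiiiiiiiiMMMMMMMMMMMMMMMMMMMMMMMMMMMMMMMMMMMMMMMMMMMMMMMMM
MMoooooooooooMMMMMMMMMMiiiiiiiiiiiiiiiiiiiiiiiiiiiiiiiiiiiii
>prot05
oooooooooooooooooooooooooooooooooooooooooooooooooooMMMMMMMMMMMMMMMMMMMMMMMMMMMMM
MMMMMiiiiiiiiiiiiiiiiiiiiiiiiiiiiiiiiiiiiiiiiiMMMMMMMMMMMMMMMMMMMMMMMMoooooooMMM
MMMMMMMMMMMiiiiiiiiiiiiMMMMMMMMMMMMMMMMMoMMMMMMMMMMMMMMMMMiiiiiiiiiiiiiiiiiiiiii
iiiiMMMMMMMMooooooooooooooooooooooooMMMMMMMMMMMMMiiiiiiiiiii
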