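>prot01
EERRERRRRLLFFLFFFLFFRFFFFLLFLLEERLLLRFFFRLFFFLFFFFLFFLFRRERRLLERFRRRRFREEEEEEERR
EFEERERERRREFRRRELFFLFLFFLFLRRRLFFRRELLLEFFFFFFLELFLLRFEFLFFFEERFFRREEEREERRLRRE
RERRRRFLFFLFFRFERREEEFEREELEEFEFEELFFFFLFFELFLFEFFFFFFFFFFFRLFLFLRLLFLFLFEERRFRR
FLREEEEREREERRFEFEEEEFFERFLFEFFFFFFFFLLFFELRRRERRRRFFELFEEEE
>prot02
RELFRFLRRRREREEELEFFFFFFFFRRRLRREREFRRLEERRRRFLFLFLEFLFFFLFLFFFLFFFFFLREFLEFFLLF
FEELFFFLLFFFEFRLLFEEFLFEEREEEERRELREEEREEERRREREEEERFFFFELFFFLFFFFFRRFLFLFFLLRRR
RRFLRERRREEERLRRRRRRRRRRRFFFFRRFFREEERERERRLFLFFFFFFFERRERFEEREEERERRERERRLRRLLR
FLLFELFLFLFFFFFLFLRFFFFFFLLLFFFLFFFEERRRRELRERRRRLFEELRRFLRR
>prot03
RRREFEERFFFLFLFFLFFRERRERRRRLREFRERERREFFLFFFLLFLLFFFLREEFEEEELLLFFFFRERRERRRERR
RFEEFFELFFFFLLFLFFLLRRRLRFEREFEEFFFFLRFREFERRRERFRRRRRRRRLREFREELRRRRRLRERRRLERL
ERFLFFLFFELLFFLFFRFFFLLRFLFLEFFFFFLLLFRFFFFLFLFFFLLFFLFRLFRELFFLFRERRRRRRRFFEERL
RRLRRFEFRRRRLERERRREERRRRREELFLFLLFRFLFLLFLFFFFLLLFFLLLFFFEF
>prot04
RRRRELFRLRRFFFFLEFFFFLFELEEELRELLERRFLRRFFLRLFFRLRRRRERFRERRREFFLFLLLLFLELLLFLFF
LFELLFLFFLLLLLFFFFFFLELEEFFFFFRLLLFFEFRRELRRRRRRRERFFLFFLLFFEFLRFLFEFEEEEEEEEEEE
EFERLFFLFFLERRERERRRRFRRLEEELRFFLFLELRLFLEFLFFFFLFLLFFLEFFFFFFFFLFFFFFLLLLFLLLLF
FFEFELLEERERLFLFEFRFFFLERLRRERRRRRERRREEERRRFEERRERERRRRRERR
>prot05
REEEEEEEFEELRFERRREEREREEEFEFRRRELLRERRFEEEEEFFRREEFFFRLFFFFLLFLFLFLLFLLFLFLLLLF
FFLLLEFRREEEEREREERERRERERRERRRERRRERREFEERRERFFLFLFLLFLFFLLLLFLLFLLLFRREEERFELL
FLLLFLFFFLFERRERREFRERRRLFFFFFLFFFRELFFFEFFFLFFFFFFLFLFFFFFRERLRRFRFFRERREREREEE
RERRFLFFFFRLEREEREFREFEREEEEREEFLEEEFFFLFREFLFFRFFRRERRLRRRF
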