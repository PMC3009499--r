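# kpaths HMM text format
ALPHABET F L R E
STATES
in i
mio1 M
mio2 M
mio3 M
mio4 M
mio5 M
mio6 M
out o
moi1 M
moi2 M
moi3 M
moi4 M
moi5 M
moi6 M
TRANSITIONS
I in 0.5
I out 0.5
in in 0.95999999999999996
in mio1 0.040000000000000001
mio1 mio2 1
mio2 mio3 1
mio3 mio4 1
mio4 mio5 1
mio5 mio6 1
mio6 mio6 0.94117647058823528
mio6 out 0.058823529411764705
out out 0.94999999999999996
out moi1 0.050000000000000003
moi1 moi2 1
moi2 moi3 1
moi3 moi4 1
moi4 moi5 1
moi5 moi6 1
moi6 in 0.0625
moi6 moi6 0.9375
EMISSIONS
in F 0.080000000000000002
in L 0.070000000000000007
in R 0.55000000000000004
in E 0.29999999999999999
mio1 F 0.55000000000000004
mio1 L 0.34999999999999998
mio1 R 0.050000000000000003
mio1 E 0.050000000000000003
mio2 F 0.55000000000000004
mio2 L 0.34999999999999998
mio2 R 0.050000000000000003
mio2 E 0.050000000000000003
mio3 F 0.55000000000000004
mio3 L 0.34999999999999998
mio3 R 0.050000000000000003
mio3 E 0.050000000000000003
mio4 F 0.55000000000000004
mio4 L 0.34999999999999998
mio4 R 0.050000000000000003
mio4 E 0.050000000000000003
mio5 F 0.55000000000000004
mio5 L 0.34999999999999998
mio5 R 0.050000000000000003
mio5 E 0.050000000000000003
mio6 F 0.55000000000000004
mio6 L 0.34999999999999998
mio6 R 0.050000000000000003
mio6 E 0.050000000000000003
out F 0.080000000000000002
out L 0.070000000000000007
out R 0.29999999999999999
out E 0.55000000000000004
moi1 F 0.55000000000000004
moi1 L 0.34999999999999998
moi1 R 0.050000000000000003
moi1 E 0.050000000000000003
moi2 F 0.55000000000000004
moi2 L 0.34999999999999998
moi2 R 0.050000000000000003
moi2 E 0.050000000000000003
moi3 F 0.55000000000000004
moi3 L 0.34999999999999998
moi3 R 0.050000000000000003
moi3 E 0.050000000000000003
moi4 F 0.55000000000000004
moi4 L 0.34999999999999998
moi4 R 0.050000000000000003
moi4 E 0.050000000000000003
moi5 F 0.55000000000000004
moi5 L 0.34999999999999998
moi5 R 0.050000000000000003
moi5 E 0.050000000000000003
moi6 F 0.55000000000000004
moi6 L 0.34999999999999998
moi6 R 0.050000000000000003
moi6 E 0.050000000000000003
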