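# kpaths HMM text format
ALPHABET F L R E
STATES
a_in i
a_mio1 M
a_mio2 M
a_mio3 M
a_mio4 M
a_mio5 M
a_mio6 M
a_out o
a_moi1 M
a_moi2 M
a_moi3 M
a_moi4 M
a_moi5 M
a_moi6 M
b_in o
b_mio1 M
b_mio2 M
b_mio3 M
b_mio4 M
b_mio5 M
b_mio6 M
b_out i
b_moi1 M
b_moi2 M
b_moi3 M
b_moi4 M
b_moi5 M
b_moi6 M
TRANSITIONS
I a_in 0.25
I a_out 0.25
I b_in 0.25
I b_out 0.25
a_in a_in 0.95999999999999996
a_in a_mio1 0.040000000000000001
a_mio1 a_mio2 1
a_mio2 a_mio3 1
a_mio3 a_mio4 1
a_mio4 a_mio5 1
a_mio5 a_mio6 1
a_mio6 a_mio6 0.94117647058823528
a_mio6 a_out 0.058823529411764705
a_out a_out 0.94999999999999996
a_out a_moi1 0.050000000000000003
a_moi1 a_moi2 1
a_moi2 a_moi3 1
a_moi3 a_moi4 1
a_moi4 a_moi5 1
a_moi5 a_moi6 1
a_moi6 a_in 0.0625
a_moi6 a_moi6 0.9375
b_in b_in 0.95999999999999996
b_in b_mio1 0.040000000000000001
b_mio1 b_mio2 1
b_mio2 b_mio3 1
b_mio3 b_mio4 1
b_mio4 b_mio5 1
b_mio5 b_mio6 1
b_mio6 b_mio6 0.94117647058823528
b_mio6 b_out 0.058823529411764705
b_out b_out 0.94999999999999996
b_out b_moi1 0.050000000000000003
b_moi1 b_moi2 1
b_moi2 b_moi3 1
b_moi3 b_moi4 1
b_moi4 b_moi5 1
b_moi5 b_moi6 1
b_moi6 b_in 0.0625
b_moi6 b_moi6 0.9375
EMISSIONS
a_in F 0.080000000000000002
a_in L 0.070000000000000007
a_in R 0.55000000000000004
a_in E 0.29999999999999999
a_mio1 F 0.55000000000000004
a_mio1 L 0.34999999999999998
a_mio1 R 0.050000000000000003
a_mio1 E 0.050000000000000003
a_mio2 F 0.55000000000000004
a_mio2 L 0.34999999999999998
a_mio2 R 0.050000000000000003
a_mio2 E 0.050000000000000003
a_mio3 F 0.55000000000000004
a_mio3 L 0.34999999999999998
a_mio3 R 0.050000000000000003
a_mio3 E 0.050000000000000003
a_mio4 F 0.55000000000000004
a_mio4 L 0.34999999999999998
a_mio4 R 0.050000000000000003
a_mio4 E 0.050000000000000003
a_mio5 F 0.55000000000000004
a_mio5 L 0.34999999999999998
a_mio5 R 0.050000000000000003
a_mio5 E 0.050000000000000003
a_mio6 F 0.55000000000000004
a_mio6 L 0.34999999999999998
a_mio6 R 0.050000000000000003
a_mio6 E 0.050000000000000003
a_out F 0.080000000000000002
a_out L 0.070000000000000007
a_out R 0.29999999999999999
a_out E 0.55000000000000004
a_moi1 F 0.55000000000000004
a_moi1 L 0.34999999999999998
a_moi1 R 0.050000000000000003
a_moi1 E 0.050000000000000003
a_moi2 F 0.55000000000000004
a_moi2 L 0.34999999999999998
a_moi2 R 0.050000000000000003
a_moi2 E 0.050000000000000003
a_moi3 F 0.55000000000000004
a_moi3 L 0.34999999999999998
a_moi3 R 0.050000000000000003
a_moi3 E 0.050000000000000003
a_moi4 F 0.55000000000000004
a_moi4 L 0.34999999999999998
a_moi4 R 0.050000000000000003
a_moi4 E 0.050000000000000003
a_moi5 F 0.55000000000000004
a_moi5 L 0.34999999999999998
a_moi5 R 0.050000000000000003
a_moi5 E 0.050000000000000003
a_moi6 F 0.55000000000000004
a_moi6 L 0.34999999999999998
a_moi6 R 0.050000000000000003
a_moi6 E 0.050000000000000003
b_in F 0.080000000000000002
b_in L 0.070000000000000007
b_in R 0.55000000000000004
b_in E 0.29999999999999999
b_mio1 F 0.55000000000000004
b_mio1 L 0.34999999999999998
b_mio1 R 0.050000000000000003
b_mio1 E 0.050000000000000003
b_mio2 F 0.55000000000000004
b_mio2 L 0.34999999999999998
b_mio2 R 0.050000000000000003
b_mio2 E 0.050000000000000003
b_mio3 F 0.55000000000000004
b_mio3 L 0.34999999999999998
b_mio3 R 0.050000000000000003
b_mio3 E 0.050000000000000003
b_mio4 F 0.55000000000000004
b_mio4 L 0.34999999999999998
b_mio4 R 0.050000000000000003
b_mio4 E 0.050000000000000003
b_mio5 F 0.55000000000000004
b_mio5 L 0.34999999999999998
b_mio5 R 0.050000000000000003
b_mio5 E 0.050000000000000003
b_mio6 F 0.55000000000000004
b_mio6 L 0.34999999999999998
b_mio6 R 0.050000000000000003
b_mio6 E 0.050000000000000003
b_out F 0.080000000000000002
b_out L 0.070000000000000007
b_out R 0.29999999999999999
b_out E 0.55000000000000004
b_moi1 F 0.55000000000000004
b_moi1 L 0.34999999999999998
b_moi1 R 0.050000000000000003
b_moi1 E 0.050000000000000003
b_moi2 F 0.55000000000000004
b_moi2 L 0.34999999999999998
b_moi2 R 0.050000000000000003
b_moi2 E 0.050000000000000003
b_moi3 F 0.55000000000000004
b_moi3 L 0.34999999999999998
b_moi3 R 0.050000000000000003
b_moi3 E 0.050000000000000003
b_moi4 F 0.55000000000000004
b_moi4 L 0.34999999999999998
b_moi4 R 0.050000000000000003
b_moi4 E 0.050000000000000003
b_moi5 F 0.55000000000000004
b_moi5 L 0.34999999999999998
b_moi5 R 0.050000000000000003
b_moi5 E 0.050000000000000003
b_moi6 F 0.55000000000000004
b_moi6 L 0.34999999999999998
b_moi6 R 0.050000000000000003
b_moi6 E 0.050000000000000003
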