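inhibitor2
 OpenBabel09232604183D

 34 36  0  0  0  0  0  0  0  0999 V2000
   -2.2448   -0.0007   -0.1106 N   0  0  0  0  0  0  0  0  0  0  0  0
   -0.8685   -0.0163   -0.0461 C   0  0  0  0  0  0  0  0  0  0  0  0
   -0.2544   -1.1931   -0.0855 N   0  0  0  0  0  0  0  0  0  0  0  0
    1.0927   -1.1565   -0.0731 C   0  0  0  0  0  0  0  0  0  0  0  0
    1.8733   -0.0058   -0.0172 C   0  0  0  0  0  0  0  0  0  0  0  0
    3.3488   -0.1109   -0.0080 C   0  0  0  0  0  0  0  0  0  0  0  0
    4.1634    0.7507   -0.7625 C   0  0  0  0  0  0  0  0  0  0  0  0
    5.5492    0.7896   -0.5785 C   0  0  0  0  0  0  0  0  0  0  0  0
    6.1626   -0.1041    0.2923 C   0  0  0  0  0  0  0  0  0  0  0  0
    5.3935   -1.0505    0.9605 C   0  0  0  0  0  0  0  0  0  0  0  0
    4.0019   -1.0479    0.8190 C   0  0  0  0  0  0  0  0  0  0  0  0
    1.1181    1.1786    0.0546 C   0  0  0  0  0  0  0  0  0  0  0  0
    1.6714    2.5642    0.1259 C   0  0  0  0  0  0  0  0  0  0  0  0
    2.7988    2.8672    0.9199 C   0  0  0  0  0  0  0  0  0  0  0  0
    3.4391    4.1115    0.8599 C   0  0  0  0  0  0  0  0  0  0  0  0
    2.8976    5.1189    0.0774 C   0  0  0  0  0  0  0  0  0  0  0  0
    3.4928    6.3402   -0.0271 O   0  0  0  0  0  0  0  0  0  0  0  0
    1.7272    4.9055   -0.6328 C   0  0  0  0  0  0  0  0  0  0  0  0
    1.1319    3.6385   -0.6185 C   0  0  0  0  0  0  0  0  0  0  0  0
    0.0171    3.4583   -1.3962 O   0  0  0  0  0  0  0  0  0  0  0  0
   -0.2430    1.1518    0.0737 N   0  0  0  0  0  0  0  0  0  0  0  0
   -2.6207   -0.8627    0.2539 H   0  0  0  0  0  0  0  0  0  0  0  0
   -2.5925    0.8705    0.2657 H   0  0  0  0  0  0  0  0  0  0  0  0
    1.5482   -2.1431   -0.1238 H   0  0  0  0  0  0  0  0  0  0  0  0
    3.7181    1.4629   -1.4563 H   0  0  0  0  0  0  0  0  0  0  0  0
    6.1414    1.5368   -1.1011 H   0  0  0  0  0  0  0  0  0  0  0  0
    7.2376   -0.0651    0.4470 H   0  0  0  0  0  0  0  0  0  0  0  0
    5.8713   -1.7748    1.6159 H   0  0  0  0  0  0  0  0  0  0  0  0
    3.4317   -1.7719    1.3989 H   0  0  0  0  0  0  0  0  0  0  0  0
    3.2372    2.1051    1.5618 H   0  0  0  0  0  0  0  0  0  0  0  0
    4.3602    4.2584    1.4150 H   0  0  0  0  0  0  0  0  0  0  0  0
    4.3154    6.3314    0.4897 H   0  0  0  0  0  0  0  0  0  0  0  0
    1.3110    5.7156   -1.2229 H   0  0  0  0  0  0  0  0  0  0  0  0
   -0.3975    4.3211   -1.5562 H   0  0  0  0  0  0  0  0  0  0  0  0
  1  2  1  0  0  0  0
  1 22  1  0  0  0  0
  1 23  1  0  0  0  0
  2  3  1  0  0  0  0
  2 21  2  0  0  0  0
  3  4  2  0  0  0  0
  4  5  1  0  0  0  0
  4 24  1  0  0  0  0
  5  6  1  0  0  0  0
  5 12  2  0  0  0  0
  6  7  1  0  0  0  0
  6 11  2  0  0  0  0
  7  8  2  0  0  0  0
  7 25  1  0  0  0  0
  8  9  1  0  0  0  0
  8 26  1  0  0  0  0
  9 10  2  0  0  0  0
  9 27  1  0  0  0  0
 10 11  1  0  0  0  0
 10 28  1  0  0  0  0
 11 29  1  0  0  0  0
 12 13  1  0  0  0  0
 12 21  1  0  0  0  0
 13 14  1  0  0  0  0
 13 19  2  0  0  0  0
 14 15  2  0  0  0  0
 14 30  1  0  0  0  0
 15 16  1  0  0  0  0
 15 31  1  0  0  0  0
 16 17  1  0  0  0  0
 16 18  2  0  0  0  0
 17 32  1  0  0  0  0
 18 19  1  0  0  0  0
 18 33  1  0  0  0  0
 19 20  1  0  0  0  0
 20 34  1  0  0  0  0
M  END
$$$$
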