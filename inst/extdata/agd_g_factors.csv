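# g-factors (mGy AGD per mGy incident air kerma) on a (breast thickness, HVL) grid,
# per the EUREF average-glandular-dose formalism for a 50%-glandular standard breast.
# rows: breast thickness (mm); columns: HVL (mm Al). Version 1.
thickness_mm,0.30,0.35,0.40,0.45,0.50,0.55,0.60
20,0.390,0.433,0.473,0.509,0.543,0.573,0.587
30,0.274,0.309,0.342,0.374,0.406,0.437,0.466
40,0.207,0.235,0.261,0.289,0.318,0.346,0.374
45,0.183,0.208,0.232,0.258,0.285,0.311,0.339
50,0.164,0.187,0.209,0.232,0.258,0.287,0.310
60,0.135,0.154,0.172,0.192,0.214,0.236,0.261
70,0.114,0.130,0.145,0.163,0.177,0.202,0.224
80,0.098,0.112,0.126,0.140,0.154,0.175,0.195
90,0.0859,0.0981,0.1106,0.1233,0.1357,0.1543,0.1723
100,0.0763,0.0873,0.0986,0.1096,0.1207,0.1375,0.1540
110,0.0687,0.0786,0.0887,0.0988,0.1088,0.1240,0.1385
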