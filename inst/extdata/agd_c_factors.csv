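# c-factors correcting for the typical glandularity of a breast of given
# compressed thickness (screening age group 50-64), per the EUREF
# average-glandular-dose formalism. rows: breast thickness (mm);
# columns: HVL (mm Al). Version 1.
thickness_mm,0.35,0.60
20,0.889,0.910
30,0.940,0.952
40,1.000,1.000
45,1.021,1.016
50,1.045,1.036
60,1.102,1.085
70,1.153,1.127
80,1.195,1.162
90,1.230,1.192
100,1.258,1.217
110,1.282,1.238
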