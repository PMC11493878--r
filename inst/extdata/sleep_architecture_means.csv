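parameter,BL_CI,BL_HC,E1_CI,E1_HC,E2_CI,E2_HC,E3_CI,E3_HC
N1,109.310,91.970,109.750,88.777,105.406,89.833,98.687,91.166
N2,170.343,154.944,163,183.277,178.375,167.527,188.093,177.305
N3,18.8125,38.444,19.281,32.333,18.968,40.583,16.437,40.611
REM,44.625,45.666,47.7812,61.861,49.718,60.611,55.437,65.277
W,148.531,128.222,147.968,118.694,119.687,106.638,129.906,108.111
TST,343.093,331.027,339.812,366.250,352.468,358.555,358.656,374.361
SL,13.2187,17.805,17.375,14.861,11.156,16.777,11.093,17.027
SE,70.219,73.399,69.755,75.701,75.032,77.454,73.576,77.902
WASO,135.968,110.916,131.093,104.333,109.031,90.361,119.312,91.583
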