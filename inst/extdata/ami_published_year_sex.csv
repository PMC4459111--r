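group,year,n_total,n_ed,ed_percent,ed_ci_low,ed_ci_high,n_invasive,invasive_percent,invasive_ci_low,invasive_ci_high
Total,2007,66883,38118,57.0,56.6,57.4,15342,22.9,22.6,23.3
Total,2008,62331,34350,55.1,54.7,55.5,15741,25.3,24.9,25.6
Total,2009,61002,31698,52.0,51.6,52.4,16126,26.4,26.1,26.8
Total,2010,57129,29466,51.6,51.2,52.0,16773,29.4,29.0,29.7
Total,2011,47656,24001,50.4,49.9,50.8,17505,36.7,36.3,37.2
Male,2007,37521,22136,59.0,58.5,59.5,10848,28.9,28.5,29.4
Male,2008,34814,20135,57.8,57.3,58.4,11190,32.1,31.7,32.6
Male,2009,34388,18884,54.9,54.4,55.4,11544,33.6,33.1,34.1
Male,2010,32176,17928,55.7,55.2,56.3,12136,37.7,37.2,38.2
Male,2011,27182,15161,55.8,55.2,56.4,12637,46.5,45.9,47.1
Female,2007,29362,15982,54.4,53.9,55.0,4494,15.3,14.9,15.7
Female,2008,27517,14215,51.7,51.1,52.2,4551,16.5,16.1,17.0
Female,2009,26614,12814,48.1,47.5,48.7,4582,17.2,16.8,17.7
Female,2010,24953,11538,46.2,45.6,46.9,4637,18.6,18.1,19.1
Female,2011,20474,8840,43.2,42.5,43.9,4868,23.8,23.2,24.4
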