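variable,group,n_episodes,n_ed,ed_row_percent,n_invasive,invasive_row_percent
total,Total,295001,157633,53.4,81487,27.6
sex,Male,166081,94244,56.7,58355,35.1
sex,Female,128920,63389,49.2,23132,17.9
age,0-9,341,153,44.9,2,0.6
age,10-19,2053,820,39.9,4,0.2
age,20-29,4710,2171,46.1,179,3.8
age,30-39,11503,6136,53.3,2332,20.3
age,40-49,31631,17755,56.1,10640,33.6
age,50-59,50333,28248,56.1,19018,37.8
age,60-69,64707,34383,53.1,21556,33.3
age,70-79,80912,42691,52.8,20696,25.6
age,≥80,48791,25276,51.8,7060,14.5
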