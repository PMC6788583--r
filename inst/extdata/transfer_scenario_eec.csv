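scenario_id,replicate,value_ppm,noe
1,1,454,FALSE
1,2,424,FALSE
1,3,410,FALSE
1,4,430,FALSE
1,5,553,FALSE
2,1,5,FALSE
2,2,8,FALSE
2,3,4,FALSE
2,4,5,FALSE
2,5,6,FALSE
3,1,NA,TRUE
3,2,NA,TRUE
3,3,NA,TRUE
3,4,NA,TRUE
3,5,NA,TRUE
4,1,12,FALSE
4,2,14,FALSE
4,3,13,FALSE
5,1,33,FALSE
5,2,27,FALSE
5,3,28,FALSE
6,1,3,FALSE
6,2,2,FALSE
6,3,2,FALSE
7,1,6,FALSE
7,2,5,FALSE
7,3,5,FALSE
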