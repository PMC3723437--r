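participant,day,TI,TW
1,1,0.37,0.47
1,2,0.42,0.67
1,3,0.45,0.55
1,4,0.22,0.39
1,5,0.35,0.44
2,1,0.5,0.5
2,2,0.07,0.09
2,3,0.42,0.45
2,4,0.6,0.7
2,5,0.6,0.66
3,1,0.2,0.3
3,2,0.57,0.62
3,3,0.26,0.75
3,4,0.7,0.9
3,5,0.4,0.9
4,1,0.62,0.8
4,2,0.61,0.8
4,3,0.38,0.45
4,4,0.4,0.6
4,5,0.58,0.65
5,1,0.3,0.85
5,2,0.4,0.7
5,3,0.3,0.7
5,4,0.4,0.8
5,5,0.3,0.85
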