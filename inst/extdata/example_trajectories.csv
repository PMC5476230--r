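id,occasion,age,height
1,1,0.01,50.2
1,2,2.41,72.3
1,3,5.12,95.8
1,4,7.55,117.9
1,5,9.94,139.6
2,1,-0.02,48.7
2,2,2.62,70.9
2,3,4.88,92.1
2,4,7.41,115.0
2,5,10.23,141.2
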