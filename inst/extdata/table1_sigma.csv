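pairing,stratum,sigma
1v2,250,7.30
1v2,500,7.20
1v2,1000,6.91
1v2,2000,7.22
1v2,4000,7.68
1v2,8000,8.88
1v2,total,7.88
1v2,mean,5.42
1v3,250,12.03
1v3,500,10.43
1v3,1000,9.28
1v3,2000,10.46
1v3,4000,10.77
1v3,8000,10.05
1v3,total,10.66
1v3,mean,7.59
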