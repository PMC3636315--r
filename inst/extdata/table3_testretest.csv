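study,series,n,f250,f500,f1000,f2000,f4000,f8000
Brown1948,,30,5.3,4.4,5.8,4.5,5.4,7.1
Erlandsson1979,,10,,6.3,6.2,4.7,5.3,10.4
Landry1999,I,20,5.0,4.6,5.2,4.1,4.3,6.0
Landry1999,II,10,8.5,7.9,5.2,6.4,9.5,6.9
Landry1999,III,10,5.9,5.4,6.4,2.1,6.7,7.1
Landry1999,IV,20,8.8,7.7,4.6,5.5,2.9,3.6
Landry1999,V,10,7.1,4.4,7.4,5.5,2.6,5.4
Landry1999,VI,10,9.3,4.6,3.3,5.3,9.0,9.4
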