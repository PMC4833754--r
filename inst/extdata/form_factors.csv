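element,Z,a1,a2,a3,a4,b1,b2,b3,b4,c,V
H,1,0.493002,0.322912,0.140191,0.040810,10.5109,26.1257,3.14236,57.7997,0.003038,5.15
C,6,2.310000,1.020000,1.588600,0.865000,20.8439,10.2075,0.56870,51.6512,0.215600,16.44
N,7,12.212600,3.132200,2.012500,1.166300,0.0057,9.8933,28.99750,0.5826,-11.529000,2.49
O,8,3.048500,2.286800,1.546300,0.867000,13.2771,5.7011,0.32390,32.9089,0.250800,9.13
P,15,6.434500,4.179100,1.780000,1.490800,1.9067,27.1570,0.52600,68.1645,1.114900,5.73
S,16,6.905300,5.203400,1.437900,1.586300,1.4679,22.2151,0.25360,56.1720,0.866900,19.86
FE,26,11.769500,7.357300,3.522200,2.304500,4.7611,0.3072,15.35350,76.8805,1.036900,7.99
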