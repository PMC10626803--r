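variable,group,n,mean,sd
alps_right,HC,41,1.63,0.18
alps_right,EM,32,1.64,0.17
alps_right,CM,24,1.77,0.23
alps_left,EM,32,1.59,0.15
alps_left,CM,24,1.65,0.16
age,HC,41,36.0,10.9
age,EM,32,34.8,15.4
age,CM,24,34.8,16.8
bmi,HC,41,22.4,2.7
bmi,EM,32,23.3,4.0
bmi,CM,24,22.8,3.3
hit6,EM,25,64.2,6.8
hit6,CM,23,68.0,5.5
psqi,EM,25,8.5,4.8
psqi,CM,23,9.1,4.7
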