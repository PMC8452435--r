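method,analyte,mean_ug_g,sd_ug_g,n
ultrasonic,A,44.8,0.5,3
ultrasonic,C,151.7,1.2,3
ultrasonic,G,185.9,0.2,3
ultrasonic,I,37.0,0.8,3
ultrasonic,U,108.7,0.6,3
ultrasonic,dA,6.6,0.2,3
ultrasonic,dC,13.6,0.4,3
ultrasonic,dG,9.6,0.1,3
ultrasonic,dU,4.1,0.1,3
boiling_water,A,45.1,0.4,3
boiling_water,C,152.5,1.7,3
boiling_water,G,188.1,1.0,3
boiling_water,I,36.7,0.2,3
boiling_water,U,108.6,0.9,3
boiling_water,dA,6.5,0.2,3
boiling_water,dC,13.4,0.2,3
boiling_water,dG,9.5,0.2,3
boiling_water,dU,4.2,0.0,3
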