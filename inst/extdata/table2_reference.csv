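subunit,variant,point,reference,value,derivable_from_profiles
beta5,Velec(ON),TS3,E-I2,8.9,inconsistent
beta5,Velec(ON),E-PC,E-I2,-48.6,yes
beta5,Velec(OFF),TS3,E-I2,27.4,yes
beta5,Velec(OFF),E-PC,E-I2,16.4,yes
beta5,Velec(D17),TS3,E-I2,16.0,yes
beta5,Velec(D17),E-PC,E-I2,-1.6,yes
beta5,Velec(D17&WAT),TS3,E-I2,10.1,no
beta5,Velec(D17&WAT),E-PC,E-I2,-35.1,no
beta2,Velec(ON),TS3,E-I2,11.3,yes
beta2,Velec(ON),E-PC,E-I2,-44.7,yes
beta2,Velec(OFF),TS3,E-I2,27.4,yes
beta2,Velec(OFF),E-PC,E-I2,4.4,yes
beta2,Velec(D17),TS3,E-I2,16.5,yes
beta2,Velec(D17),E-PC,E-I2,-10.5,yes
beta2,Velec(D17&WAT),TS3,E-I2,13.1,no
beta2,Velec(D17&WAT),E-PC,E-I2,-30.6,no
beta1,Velec(ON),TS3,E-I2,13.0,yes
beta1,Velec(ON),E-PC,E-I2,-49.0,yes
beta1,Velec(OFF),TS3,E-I2,23.4,yes
beta1,Velec(OFF),E-PC,E-I2,-3.0,yes
beta1,Velec(D17),TS3,E-I2,17.0,yes
beta1,Velec(D17),E-PC,E-I2,-21.0,yes
beta1,Velec(D17&WAT),TS3,E-I2,8.1,no
beta1,Velec(D17&WAT),E-PC,E-I2,-73.5,no
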