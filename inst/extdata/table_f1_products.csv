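product,dimension,polarity,A,B
mouthwash,breath,higher_better,4.5,7.2
mouthwash,germs,higher_better,77,56
exercise_class,fee,lower_better,9.49,6.49
exercise_class,calories,higher_better,356,259
chocolate,amount,higher_better,26,33
chocolate,variety,higher_better,9,5
gps,update,higher_better,3.04,5.62
gps,accuracy,lower_better,4.97,7.83
battery,price,lower_better,19.93,13.49
battery,talk_time,higher_better,14.55,9.25
light_bulb,life,higher_better,1309,1923
light_bulb,price,lower_better,1.35,2.50
air_purifier,noise,lower_better,64.7,39.3
air_purifier,efficiency,higher_better,325,203
strawberry,quantity,higher_better,407,452
strawberry,price,lower_better,2.58,2.85
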