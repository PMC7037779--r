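block,category,prop_fatalities,prop_injuries
gear,neutral,0.1644,0.1771
gear,gear1,0.0112,0.0141
gear,gear2,0.0226,0.0306
gear,gear3,0.0513,0.0621
gear,gear4,0.0557,0.0483
gear,gear5plus,0.0867,0.0675
gear,reverse,0.0069,0.0052
gear,unclear,0.4102,0.3435
gear,automatic,0.1909,0.2516
light,day,0.5162,0.6100
light,night_lit,0.1807,0.2020
light,night_unlit,0.2442,0.1449
light,dusk,0.0324,0.0178
light,dawn,0.0265,0.0253
weather,sunny,0.7398,0.7356
weather,cloudy,0.1438,0.1526
weather,rainy,0.1045,0.1034
weather,snowy,0.0046,0.0037
weather,foggy,0.0053,0.0036
weather,windy,0.0003,0.0003
weather,sandstorm,0.0002,0.0002
weather,hail,0.0000,0.0000
weather,smoggy,0.0002,0.0000
weather,other,0.0013,0.0007
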