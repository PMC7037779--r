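type,label,accidents,pct_accidents,fatalities,pct_fatalities,injuries,pct_injuries
pedestrian_single_vehicle,Pedestrian-single vehicle collision on a road,23288,11.47,8558,13.42,18931,9.03
obstacle_single_vehicle,Obstacle-single vehicle collision on a road,4179,2.06,1904.5,2.99,3765,1.80
roadside_single_vehicle,Single vehicle collision beside the road,35015,17.24,15179.5,23.80,31175,14.87
head_on,Head-on collision,14495,7.14,5064,7.94,18661,8.90
sideswipe,Sideswipe collision,14135,6.96,3197,5.01,15497,7.39
angle,Angle collision,83083,40.92,18955,29.72,92727,44.23
rear_end,Rear-end collision,15481,7.62,6111,9.58,16409,7.83
other_two_vehicle,Other collision with two vehicles,9904,4.88,3492,5.48,9033,4.31
other,All other collision,3467,1.71,861,1.35,3456,1.65
total,Total,203049,100,63772,100,209645,100
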