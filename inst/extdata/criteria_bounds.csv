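criterion,level,b_min,b_max
PM2.5,I,0,35
PM2.5,II,35,75
PM2.5,III,75,115
PM2.5,IV,115,150
PM2.5,V,150,250
PM2.5,VI,250,NA
PM10,I,0,50
PM10,II,50,150
PM10,III,150,250
PM10,IV,250,350
PM10,V,350,420
PM10,VI,420,NA
O3,I,0,10
O3,II,10,160
O3,III,160,215
O3,IV,215,265
O3,V,265,800
O3,VI,800,NA
CO,I,0,2
CO,II,2,4
CO,III,4,14
CO,IV,14,24
CO,V,24,36
CO,VI,36,NA
NO2,I,0,40
NO2,II,40,80
NO2,III,80,180
NO2,IV,180,280
NO2,V,280,565
NO2,VI,565,NA
SO2,I,0,50
SO2,II,50,150
SO2,III,150,250
SO2,IV,250,475
SO2,V,475,800
SO2,VI,800,NA
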