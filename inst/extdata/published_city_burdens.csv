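city,country,population,max_si,no2,no2_lo,no2_hi,o3,o3_lo,o3_hi,pm25,pm25_lo,pm25_hi,pm10,pm10_lo,pm10_hi
Amsterdam,Netherlands,1128715,79.63,-5.9,-7.2,-4.6,0.8,0.6,1.1,-1.8,-2.1,-1.6,-1.4,-1.5,-1.2
Ankara,Turkey,3002440,77.78,-8.3,-10.1,-6.5,-1.3,-1.7,-0.9,-0.6,-0.7,-0.5,-0.7,-0.8,-0.6
Athens,Greece,3315199,84.26,-40.1,-48.8,-31.2,-0.7,-1.0,-0.5,-10.0,-11.4,-8.8,-7.8,-8.7,-6.9
Barcelona,Spain,3832012,85.19,-39.2,-47.7,-30.5,-1.2,-1.6,-0.8,-12.2,-13.9,-10.7,-9.3,-10.3,-8.3
Belgrade,Serbia,1106870,100,-1.6,-2.0,-1.3,-2.5,-3.2,-1.7,-1.4,-1.6,-1.2,-1.0,-1.2,-0.9
Berlin,Germany,3271872,76.85,-9.6,-11.6,-7.4,-1.6,-2.1,-1.1,-4.7,-5.4,-4.1,-3.5,-3.8,-3.1
Bern,Switzerland,197760,73.15,-0.5,-0.6,-0.4,-0.3,-0.5,-0.2,-0.5,-0.6,-0.4,-0.4,-0.4,-0.3
Birmingham,United Kingdom,2426863,75.93,-8.9,-10.8,-6.9,1.0,0.7,1.3,-4.2,-4.8,-3.7,-3.1,-3.5,-2.8
Bratislava,Slovakia,352002,87.04,-1.0,-1.2,-0.8,-0.4,-0.6,-0.3,-0.5,-0.6,-0.4,-0.4,-0.4,-0.3
Brussels,Belgium,1381517,81.48,-10.4,-12.7,-8.1,1.4,0.9,1.8,-3.2,-3.7,-2.8,-2.4,-2.7,-2.1
Bucharest,Romania,1774128,87.04,-9.5,-11.5,-7.4,-2.4,-3.2,-1.7,-2.8,-3.1,-2.4,-2.2,-2.4,-1.9
Budapest,Hungary,1758468,76.85,-7.3,-8.9,-5.7,-2.9,-3.9,-2.0,-2.8,-3.2,-2.4,-2.3,-2.5,-2.0
Cologne,Germany,1508677,76.85,-10.1,-12.3,-7.8,0.6,0.4,0.8,-4.4,-5.0,-3.8,-3.2,-3.6,-2.9
Copenhagen,Denmark,1225959,72.22,-4.5,-5.5,-3.5,0.5,0.4,0.7,-1.2,-1.4,-1.1,-1.0,-1.1,-0.9
Dublin,Ireland,1004263,90.74,-3.3,-4.0,-2.6,0.3,0.2,0.4,-1.0,-1.2,-0.9,-0.8,-0.9,-0.7
Hamburg,Germany,1596992,76.85,-7.3,-8.9,-5.7,0.3,0.2,0.4,-2.4,-2.8,-2.1,-1.9,-2.1,-1.7
Helsinki,Finland,907386,60.19,-1.9,-2.3,-1.5,0.1,0.1,0.1,-0.5,-0.6,-0.4,-0.7,-0.8,-0.7
Lisbon,Portugal,1958521,87.96,-18.9,-23.0,-14.7,0.3,0.2,0.4,-11.4,-13.1,-10.0,-10.6,-11.8,-9.4
Ljubljana,Slovenia,250335,89.81,-0.7,-0.8,-0.5,-0.4,-0.6,-0.3,-0.4,-0.5,-0.4,-0.3,-0.3,-0.3
London,United Kingdom,9609627,75.93,-37.9,-46.1,-29.5,4.9,3.4,6.5,-13.9,-15.8,-12.2,-10.5,-11.7,-9.3
Luxembourg,Luxembourg,119160,79.63,-0.4,-0.4,-0.3,-0.1,-0.1,-0.1,-0.2,-0.3,-0.2,-0.2,-0.2,-0.2
Lyon,France,1152368,87.96,-6.7,-8.2,-5.2,-1.0,-1.3,-0.7,-2.6,-3.0,-2.3,-2.0,-2.2,-1.8
Madrid,Spain,4894295,85.19,-38.8,-47.2,-30.2,-3.4,-4.5,-2.3,-7.7,-8.7,-6.7,-6.1,-6.7,-5.4
Marseille,France,909727,87.96,-3.2,-3.8,-2.5,-1.5,-1.9,-1.0,-1.7,-1.9,-1.5,-1.3,-1.4,-1.1
Milan,Italy,3011030,93.52,-36.7,-44.7,-28.6,-6.1,-8.0,-4.1,-18.1,-20.6,-15.8,-12.6,-14.0,-11.2
Monaco,France,59433,87.96,-0.2,-0.2,-0.1,-0.2,-0.2,-0.1,-0.1,-0.2,-0.1,-0.1,-0.1,-0.1
Munich,Germany,1573652,76.85,-5.5,-6.7,-4.3,-1.5,-1.9,-1.0,-3.1,-3.5,-2.7,-2.3,-2.5,-2.0
Naples,Italy,3167668,93.52,-29.9,-36.4,-23.3,-1.9,-2.6,-1.3,-8.2,-9.4,-7.2,-5.9,-6.5,-5.2
Nicosia,Cyprus,228923,94.44,-0.3,-0.4,-0.2,-0.3,-0.4,-0.2,-0.2,-0.2,-0.1,-0.1,-0.1,-0.1
Oslo,Norway,782172,79.63,-0.7,-0.9,-0.6,-0.1,-0.1,-0.0,-0.2,-0.2,-0.2,-0.2,-0.2,-0.1
Paris,France,9711652,87.96,-69.2,-84.2,-53.8,3.5,2.4,4.6,-23.2,-26.5,-20.4,-17.4,-19.3,-15.4
Prague,Czech Republic,1126681,82.41,-2.6,-3.2,-2.1,-1.0,-1.3,-0.7,-1.6,-1.8,-1.4,-1.1,-1.2,-1.0
Pristina,Kosovo,196913,92.59,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA
Reykjavik,Iceland,184357,53.7,-0.1,-0.1,-0.1,0.0,0.0,0.0,-0.0,-0.0,-0.0,-0.0,-0.0,-0.0
Riga,Latvia,556672,65.74,-0.6,-0.8,-0.5,-0.4,-0.5,-0.3,-0.4,-0.4,-0.3,-0.3,-0.3,-0.3
Rome,Italy,2342860,93.52,-18.4,-22.4,-14.3,-5.8,-7.7,-4.0,-6.8,-7.7,-5.9,-4.8,-5.3,-4.3
Sarajevo,Bosnia and Herzegovina,371884,92.59,-0.4,-0.5,-0.3,-0.7,-1.0,-0.5,-0.3,-0.4,-0.3,-0.2,-0.3,-0.2
Sofia,Bulgaria,926881,73.15,-3.5,-4.3,-2.7,-1.4,-1.9,-1.0,-1.1,-1.3,-1.0,-0.8,-0.9,-0.8
Stockholm,Sweden,1305076,46.3,-1.8,-2.2,-1.4,-0.2,-0.3,-0.1,-0.7,-0.8,-0.6,-1.1,-1.2,-0.9
Tallinn,Estonia,344511,77.78,-0.5,-0.7,-0.4,-0.1,-0.1,-0.1,-0.1,-0.2,-0.1,-0.1,-0.1,-0.1
Tirana,Albania,719252,89.81,-1.5,-1.8,-1.1,-0.9,-1.1,-0.6,-0.7,-0.7,-0.6,-0.5,-0.6,-0.4
Turin,Italy,1205385,93.52,-13.3,-16.2,-10.3,-3.6,-4.8,-2.5,-6.8,-7.8,-6.0,-4.9,-5.4,-4.3
Valencia,Spain,1393120,85.19,-8.0,-9.7,-6.2,-1.9,-2.6,-1.3,-3.3,-3.7,-2.9,-2.5,-2.8,-2.2
Vienna,Austria,1856676,85.19,-6.1,-7.4,-4.7,-1.8,-2.4,-1.2,-3.1,-3.5,-2.7,-2.3,-2.5,-2.0
Vilnius,Lithuania,355430,87.04,-0.8,-1.0,-0.6,-0.2,-0.3,-0.1,-0.3,-0.4,-0.3,-0.2,-0.3,-0.2
Warsaw,Poland,1789294,83.33,-7.5,-9.2,-5.9,-1.0,-1.3,-0.7,-2.9,-3.3,-2.5,-2.0,-2.2,-1.8
Zagreb,Croatia,660653,96.3,-1.9,-2.3,-1.4,-1.5,-1.9,-1.0,-1.2,-1.4,-1.1,-1.0,-1.1,-0.9
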