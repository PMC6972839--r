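pmu,season,n_birds,n_locs,modeled
Battle Mountain,spring,6,30,0
Battle Mountain,summer_fall,11,42,0
Battle Mountain,winter,10,35,0
Buffalo-Skedaddle,spring,207,1748,1
Buffalo-Skedaddle,summer_fall,174,1886,1
Buffalo-Skedaddle,winter,149,565,1
Cortez-Diamond-3Bar,spring,309,4142,1
Cortez-Diamond-3Bar,summer_fall,216,956,1
Cortez-Diamond-3Bar,winter,196,541,1
Desatoya,spring,26,772,0
Desatoya,summer_fall,28,482,0
Desatoya,winter,15,520,0
Desert-Tuscarora,spring,135,2556,1
Desert-Tuscarora,summer_fall,115,2878,1
Desert-Tuscarora,winter,55,1519,1
Fish Creek,spring,10,70,0
Fish Creek,summer_fall,19,126,0
Fish Creek,winter,16,64,0
GBNP E,spring,0,0,0
GBNP E,summer_fall,4,8,0
GBNP E,winter,4,26,0
Gollaher-O'Neil,spring,114,1523,1
Gollaher-O'Neil,summer_fall,120,902,1
Gollaher-O'Neil,winter,84,307,1
Lincoln-Schell-Snake,spring,57,373,1
Lincoln-Schell-Snake,summer_fall,81,509,1
Lincoln-Schell-Snake,winter,67,378,1
Lone Willow,spring,76,103,0
Lone Willow,summer_fall,73,94,0
Lone Willow,winter,73,130,0
Midway,spring,60,1616,1
Midway,summer_fall,46,1646,1
Midway,winter,22,1770,0
North SWIP,spring,121,1348,1
North SWIP,summer_fall,141,1644,1
North SWIP,winter,74,1148,1
Reese River,spring,10,19,0
Reese River,summer_fall,10,32,0
Reese River,winter,9,18,0
Santa Rosa,spring,10,18,0
Santa Rosa,summer_fall,9,23,0
Santa Rosa,winter,9,17,0
Sheldon,spring,18,18,0
Sheldon,summer_fall,19,54,0
Sheldon,winter,21,39,0
Shoshone,spring,11,65,0
Shoshone,summer_fall,12,66,0
Shoshone,winter,10,76,0
Snake,spring,5,38,0
Snake,summer_fall,4,7,0
Snake,winter,0,0,0
South Fork-Ruby V.,spring,25,76,0
South Fork-Ruby V.,summer_fall,20,47,0
South Fork-Ruby V.,winter,32,66,0
South SWIP,spring,60,1399,1
South SWIP,summer_fall,42,1246,1
South SWIP,winter,42,729,1
Steptoe,spring,18,134,0
Steptoe,summer_fall,15,88,0
Steptoe,winter,14,80,0
Toiyabe,spring,95,2276,1
Toiyabe,summer_fall,71,2676,1
Toiyabe,winter,52,1836,1
Virginia Mtns,spring,96,850,1
Virginia Mtns,summer_fall,87,341,1
Virginia Mtns,winter,53,62,0
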