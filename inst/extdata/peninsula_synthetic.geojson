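{
"type": "Feature",
"properties": {"name": "synthetic coastal peninsula (generated fixture, not real cartography)", "units": "m"},
"geometry": {"type": "Polygon", "coordinates": [[
[98327,58235],
[97539,59674],
[96246,60848],
[94544,61770],
[92571,62488],
[90464,63073],
[88336,63597],
[86243,64113],
[84175,64633],
[82067,65122],
[79822,65497],
[77346,65650],
[74577,65469],
[71517,64873],
[68233,63833],
[64844,62392],
[61500,60659],
[58335,58796],
[55441,56986],
[52834,55400],
[50456,54155],
[48186,53297],
[45870,52790],
[43371,52520],
[40602,52326],
[37562,52032],
[34339,51482],
[31098,50575],
[28047,49277],
[25392,47628],
[23286,45722],
[21795,43688],
[20882,41652],
[20412,39716],
[20186,37937],
[19978,36322],
[19589,34836],
[18882,33416],
[17811,31995],
[16413,30519],
[14797,28958],
[13106,27313],
[11480,25602],
[10019,23854],
[8771,22093],
[7723,20327],
[6828,18546],
[6026,16726],
[5278,14846],
[4592,12899],
[4033,10907],
[3713,8929],
[3771,7056],
[4337,5396],
[5498,4054],
[7277,3109],
[9617,2590],
[12398,2471],
[15457,2673],
[18629,3081],
[21781,3569],
[24834,4034],
[27779,4419],
[30665,4731],
[33570,5044],
[36567,5477],
[39693,6172],
[42922,7254],
[46161,8803],
[49266,10824],
[52072,13246],
[54440,15925],
[56294,18675],
[57648,21303],
[58615,23641],
[59391,25581],
[60218,27092],
[61335,28221],
[62930,29073],
[65099,29792],
[67832,30524],
[71015,31391],
[74458,32471],
[77940,33792],
[81254,35333],
[84246,37049],
[86842,38879],
[89044,40774],
[90915,42701],
[92546,44651],
[94019,46628],
[95373,48637],
[96593,50672],
[97606,52707],
[98303,54690],
[98572,56556],
[98327,58235]
]]}
}

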