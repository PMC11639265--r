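840001,M,22.8744,16.442,24.4567,2.1068,9.7333,9.52,24.2756,16.9481,21.2498,5.4488,14.561,2.186,8.3601,23.5643,18.8005,8.9502,5.8764,20.544,18.3515,19.4813,23.3738,2.9486,20.6258,18.5695,3.2654,22.1337,6.3488,14.3872,7.8764,7.6372
840002,B,23.43,17.6414,2.9813,12.8796,17.145,10.9225,15.49,4.323,4.7774,12.011,3.9897,7.6652,12.9008,24.0671,11.3457,10.2953,18.1262,2.8873,20.4399,9.8913,13.7848,4.6932,14.828,18.6967,3.2708,12.9519,6.5293,8.8661,20.5218,0.4878
840003,M,7.1892,11.4707,11.9012,9.7856,0.1485,0.9839,8.369,6.5641,6.8186,4.9754,9.0078,16.7023,18.6122,18.5094,13.418,14.3582,22.5957,19.1245,4.2956,16.9809,15.0641,18.2568,19.8702,22.9517,1.8527,21.3057,13.5733,13.7083,7.711,24.914
840004,B,20.7697,17.9919,14.0303,22.6482,20.8313,24.3398,8.7014,12.8846,20.7126,17.9979,16.1585,0.056,15.498,18.3445,13.4575,14.7625,15.1067,15.6092,23.6208,19.4068,4.965,10.3262,19.2374,19.8401,1.3756,11.0978,16.2644,22.3233,4.6771,20.1196
840005,B,16.0616,23.3701,22.6056,11.2019,0.233,10.8222,9.9922,16.9064,17.3455,0.2467,19.4068,5.2538,15.6748,13.4172,0.0845,18.0054,15.8061,3.7537,7.3759,4.7373,13.4042,10.3805,22.9555,3.3766,13.3203,3.9891,8.4437,12.2753,1.2563,2.2102
840006,M,13.0014,6.4229,3.5108,20.9083,5.2311,23.9415,19.6281,24.5713,6.0516,9.4185,14.113,23.3292,5.4681,0.1067,8.9239,9.9046,23.4378,2.0526,3.7693,0.7757,4.5299,12.0337,21.5726,7.2294,2.8521,11.086,1.5707,4.3322,6.1796,21.7548
840007,B,18.4279,11.5842,24.7228,18.453,22.6697,22.1995,1.0215,19.0006,1.1226,12.8845,5.8809,23.1448,5.4534,15.243,15.3227,22.9841,21.2695,11.6285,17.9985,3.4361,11.3246,10.716,7.9585,4.9072,18.5925,24.195,11.3102,13.5986,8.8101,13.8869
840008,B,3.4099,23.5034,23.6694,20.2858,15.3139,16.0175,18.7324,14.1839,3.555,0.0892,2.295,18.3657,9.7542,20.9282,20.7321,24.0661,14.5165,19.4952,8.1359,17.0201,7.9605,3.4554,6.5186,19.6135,18.2963,12.1405,20.9769,24.0386,4.0176,10.5634
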