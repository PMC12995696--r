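experiment,network,tau1,tau2,tau3,region,mean_metric_1,mean_metric_2,printed_score
2,FCN_UNet,,,,patellar_tendon,0.8053,3.7088,74
3,FCN_UNet,0.90,0.10,,patellar_tendon,0.7970,19.6452,51
3,FCN_UNet,0.50,0.50,,patellar_tendon,0.7950,3.7514,63
3,FCN_UNet,0.10,0.90,,patellar_tendon,0.8023,3.6374,74
4,FCN_UNet,0.90,,0.10,patellar_tendon,0.7978,3.3961,78
4,FCN_UNet,0.50,,0.50,patellar_tendon,0.6804,9.5791,23
4,FCN_UNet,0.10,,0.90,patellar_tendon,0.2476,225.1707,11
5,FCN_UNet,0.80,0.10,0.10,patellar_tendon,0.7964,3.7322,66
5,FCN_UNet,0.34,0.33,0.33,patellar_tendon,0.7750,4.7159,36
5,FCN_UNet,0.50,0.25,0.25,patellar_tendon,0.7833,5.1165,42
7,PSPNet_R50c,,,,patellar_tendon,0.7981,3.2517,85
8,PSPNet_R50c,0.90,0.10,,patellar_tendon,0.8055,2.6852,98
8,PSPNet_R50c,0.50,0.50,,patellar_tendon,0.7863,3.5060,61
8,PSPNet_R50c,0.10,0.90,,patellar_tendon,0.7709,18.7295,23
9,PSPNet_R50c,0.90,,0.10,patellar_tendon,0.7928,2.7682,82
9,PSPNet_R50c,0.50,,0.50,patellar_tendon,,,2
9,PSPNet_R50c,0.10,,0.90,patellar_tendon,0.0443,246.6131,5
10,PSPNet_R50c,0.80,0.10,0.10,patellar_tendon,0.7946,2.7551,86
10,PSPNet_R50c,0.34,0.33,0.33,patellar_tendon,0.7817,3.3054,56
10,PSPNet_R50c,0.50,0.25,0.25,patellar_tendon,0.7986,2.8257,91
12,DeepLabV3+_R50c,,,,patellar_tendon,0.8094,3.6957,78
13,DeepLabV3+_R50c,0.90,0.10,,patellar_tendon,0.7940,2.9208,80
13,DeepLabV3+_R50c,0.50,0.50,,patellar_tendon,0.7860,3.4418,61
13,DeepLabV3+_R50c,0.10,0.90,,patellar_tendon,0.7841,3.9909,47
14,DeepLabV3+_R50c,0.90,,0.10,patellar_tendon,0.7945,2.8343,82
14,DeepLabV3+_R50c,0.50,,0.50,patellar_tendon,0.3923,167.3667,17
14,DeepLabV3+_R50c,0.10,,0.90,patellar_tendon,0.0334,240.4987,5
15,DeepLabV3+_R50c,0.80,0.10,0.10,patellar_tendon,0.7391,5.3529,31
15,DeepLabV3+_R50c,0.34,0.33,0.33,patellar_tendon,0.7732,3.5363,45
15,DeepLabV3+_R50c,0.50,0.25,0.25,patellar_tendon,0.7906,3.1369,74
17,UPerNet_R50c,,,,patellar_tendon,0.8029,3.2718,86
18,UPerNet_R50c,0.90,0.10,,patellar_tendon,0.7918,3.3899,70
18,UPerNet_R50c,0.50,0.50,,patellar_tendon,0.7819,3.2536,59
18,UPerNet_R50c,0.10,0.90,,patellar_tendon,0.7831,3.9731,44
19,UPerNet_R50c,0.90,,0.10,patellar_tendon,0.7836,3.3538,60
19,UPerNet_R50c,0.50,,0.50,patellar_tendon,0.4655,171.3072,17
19,UPerNet_R50c,0.10,,0.90,patellar_tendon,0.1550,239.4136,8
20,UPerNet_R50c,0.80,0.10,0.10,patellar_tendon,0.7874,3.2205,71
20,UPerNet_R50c,0.34,0.33,0.33,patellar_tendon,0.7840,3.5846,54
20,UPerNet_R50c,0.50,0.25,0.25,patellar_tendon,0.7845,3.6156,55
22,SegFormer_B2,,,,patellar_tendon,0.8089,6.4316,67
23,SegFormer_B2,0.90,0.10,,patellar_tendon,0.7906,6.6098,46
23,SegFormer_B2,0.50,0.50,,patellar_tendon,0.7776,3.5138,48
23,SegFormer_B2,0.10,0.90,,patellar_tendon,0.7802,7.6638,31
24,SegFormer_B2,0.90,,0.10,patellar_tendon,0.7912,10.7667,43
24,SegFormer_B2,0.50,,0.50,patellar_tendon,0.3655,200.8787,14
24,SegFormer_B2,0.10,,0.90,patellar_tendon,0.1771,207.4985,11
25,SegFormer_B2,0.80,0.10,0.10,patellar_tendon,0.7954,5.7781,58
25,SegFormer_B2,0.34,0.33,0.33,patellar_tendon,0.7916,8.0147,46
25,SegFormer_B2,0.50,0.25,0.25,patellar_tendon,0.7827,7.4465,35
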