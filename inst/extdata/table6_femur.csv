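experiment,network,tau1,tau2,tau3,region,mean_metric_1,mean_metric_2,printed_score
2,FCN_UNet,,,,femur,0.9660,2.3227,42
3,FCN_UNet,0.90,0.10,,femur,0.9786,3.7679,37
3,FCN_UNet,0.50,0.50,,femur,0.9812,1.5402,81
3,FCN_UNet,0.10,0.90,,femur,0.9822,2.9200,63
4,FCN_UNet,0.90,,0.10,femur,0.9609,2.9711,31
4,FCN_UNet,0.50,,0.50,femur,0.4721,27.3042,16
4,FCN_UNet,0.10,,0.90,femur,0.3926,150.5682,10
5,FCN_UNet,0.80,0.10,0.10,femur,0.9763,2.0188,50
5,FCN_UNet,0.34,0.33,0.33,femur,0.9763,3.6070,34
5,FCN_UNet,0.50,0.25,0.25,femur,0.9788,2.7868,46
7,PSPNet_R50c,,,,femur,0.9702,2.0397,47
8,PSPNet_R50c,0.90,0.10,,femur,0.9794,2.3428,53
8,PSPNet_R50c,0.50,0.50,,femur,0.9803,5.1285,45
8,PSPNet_R50c,0.10,0.90,,femur,0.9824,2.9178,67
9,PSPNet_R50c,0.90,,0.10,femur,0.9495,3.1453,25
9,PSPNet_R50c,0.50,,0.50,femur,0.9376,6.7885,20
9,PSPNet_R50c,0.10,,0.90,femur,0.2469,212.0505,4
10,PSPNet_R50c,0.80,0.10,0.10,femur,0.9794,1.6041,65
10,PSPNet_R50c,0.34,0.33,0.33,femur,0.9820,1.5092,89
10,PSPNet_R50c,0.50,0.25,0.25,femur,0.9812,1.5415,79
12,DeepLabV3+_R50c,,,,femur,0.9685,2.1800,45
13,DeepLabV3+_R50c,0.90,0.10,,femur,0.9782,1.7530,53
13,DeepLabV3+_R50c,0.50,0.50,,femur,0.9818,1.5184,87
13,DeepLabV3+_R50c,0.10,0.90,,femur,0.9809,1.6359,70
14,DeepLabV3+_R50c,0.90,,0.10,femur,0.9609,2.5896,36
14,DeepLabV3+_R50c,0.50,,0.50,femur,0.5023,104.1832,16
14,DeepLabV3+_R50c,0.10,,0.90,femur,0.1513,176.5788,6
15,DeepLabV3+_R50c,0.80,0.10,0.10,femur,0.9793,1.7563,56
15,DeepLabV3+_R50c,0.34,0.33,0.33,femur,0.9813,1.5785,79
15,DeepLabV3+_R50c,0.50,0.25,0.25,femur,0.9815,1.5359,85
17,UPerNet_R50c,,,,femur,0.9635,2.6161,37
18,UPerNet_R50c,0.90,0.10,,femur,0.9785,1.6955,55
18,UPerNet_R50c,0.50,0.50,,femur,0.9821,1.4730,91
18,UPerNet_R50c,0.10,0.90,,femur,0.9822,1.5387,88
19,UPerNet_R50c,0.90,,0.10,femur,0.9562,3.0893,27
19,UPerNet_R50c,0.50,,0.50,femur,0.5432,115.2513,16
19,UPerNet_R50c,0.10,,0.90,femur,0.3514,180.5364,7
20,UPerNet_R50c,0.80,0.10,0.10,femur,0.9795,1.6491,63
20,UPerNet_R50c,0.34,0.33,0.33,femur,0.9801,1.6452,66
20,UPerNet_R50c,0.50,0.25,0.25,femur,0.9805,1.6124,71
22,SegFormer_B2,,,,femur,0.9662,2.3667,41
23,SegFormer_B2,0.90,0.10,,femur,0.9797,1.5880,70
23,SegFormer_B2,0.50,0.50,,femur,0.9825,1.4274,99
23,SegFormer_B2,0.10,0.90,,femur,0.9823,1.4687,95
24,SegFormer_B2,0.90,,0.10,femur,0.9571,2.8791,32
24,SegFormer_B2,0.50,,0.50,femur,0.4610,133.2440,12
24,SegFormer_B2,0.10,,0.90,femur,0.0402,183.7097,3
25,SegFormer_B2,0.80,0.10,0.10,femur,0.9795,1.6276,65
25,SegFormer_B2,0.34,0.33,0.33,femur,0.9824,1.3997,98
25,SegFormer_B2,0.50,0.25,0.25,femur,0.9811,1.5732,77
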