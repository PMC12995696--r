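experiment,network,tau1,tau2,tau3,region,mean_metric_1,mean_metric_2,printed_score
2,FCN_UNet,,,,patella,0.9506,2.1284,42
3,FCN_UNet,0.90,0.10,,patella,0.9479,4.8491,30
3,FCN_UNet,0.50,0.50,,patella,0.9579,2.1008,69
3,FCN_UNet,0.10,0.90,,patella,0.9579,2.2230,65
4,FCN_UNet,0.90,,0.10,patella,0.9456,1.9375,35
4,FCN_UNet,0.50,,0.50,patella,0.8668,52.9177,19
4,FCN_UNet,0.10,,0.90,patella,0.0678,235.1421,8
5,FCN_UNet,0.80,0.10,0.10,patella,0.9536,1.8303,57
5,FCN_UNet,0.34,0.33,0.33,patella,0.9544,1.8316,62
5,FCN_UNet,0.50,0.25,0.25,patella,0.9543,1.9237,57
7,PSPNet_R50c,,,,patella,0.9491,1.9942,38
8,PSPNet_R50c,0.90,0.10,,patella,0.9591,1.4592,100
8,PSPNet_R50c,0.50,0.50,,patella,0.9564,10.5598,52
8,PSPNet_R50c,0.10,0.90,,patella,0.9503,16.6173,32
9,PSPNet_R50c,0.90,,0.10,patella,0.9488,1.7166,51
9,PSPNet_R50c,0.50,,0.50,patella,0.7743,6.9485,23
9,PSPNet_R50c,0.10,,0.90,patella,0.0169,296.1988,3
10,PSPNet_R50c,0.80,0.10,0.10,patella,0.9544,1.6557,75
10,PSPNet_R50c,0.34,0.33,0.33,patella,0.9542,1.7480,65
10,PSPNet_R50c,0.50,0.25,0.25,patella,0.9558,1.5545,84
12,DeepLabV3+_R50c,,,,patella,0.9500,1.8477,43
13,DeepLabV3+_R50c,0.90,0.10,,patella,0.9534,1.8014,56
13,DeepLabV3+_R50c,0.50,0.50,,patella,0.9558,1.6854,73
13,DeepLabV3+_R50c,0.10,0.90,,patella,0.9571,1.6446,84
14,DeepLabV3+_R50c,0.90,,0.10,patella,0.9501,1.8378,45
14,DeepLabV3+_R50c,0.50,,0.50,patella,0.6536,198.0416,15
14,DeepLabV3+_R50c,0.10,,0.90,patella,0.0054,263.1601,3
15,DeepLabV3+_R50c,0.80,0.10,0.10,patella,0.9418,2.1993,30
15,DeepLabV3+_R50c,0.34,0.33,0.33,patella,0.9538,1.7805,63
15,DeepLabV3+_R50c,0.50,0.25,0.25,patella,0.9566,1.6375,84
17,UPerNet_R50c,,,,patella,0.9510,1.7820,54
18,UPerNet_R50c,0.90,0.10,,patella,0.9538,5.6898,45
18,UPerNet_R50c,0.50,0.50,,patella,0.9530,9.8339,39
18,UPerNet_R50c,0.10,0.90,,patella,0.9563,1.6848,77
19,UPerNet_R50c,0.90,,0.10,patella,0.9500,2.4410,34
19,UPerNet_R50c,0.50,,0.50,patella,0.6784,201.1679,15
19,UPerNet_R50c,0.10,,0.90,patella,0.0651,244.2843,6
20,UPerNet_R50c,0.80,0.10,0.10,patella,0.9573,1.6083,89
20,UPerNet_R50c,0.34,0.33,0.33,patella,0.9559,1.6577,78
20,UPerNet_R50c,0.50,0.25,0.25,patella,0.9572,1.6279,87
22,SegFormer_B2,,,,patella,0.9502,1.7823,50
23,SegFormer_B2,0.90,0.10,,patella,0.9575,1.5292,93
23,SegFormer_B2,0.50,0.50,,patella,0.9577,1.5733,92
23,SegFormer_B2,0.10,0.90,,patella,0.9479,17.4427,23
24,SegFormer_B2,0.90,,0.10,patella,0.9525,1.6671,64
24,SegFormer_B2,0.50,,0.50,patella,0.5608,217.9815,12
24,SegFormer_B2,0.10,,0.90,patella,0.1171,225.5293,10
25,SegFormer_B2,0.80,0.10,0.10,patella,0.9535,1.7253,63
25,SegFormer_B2,0.34,0.33,0.33,patella,0.9587,1.5236,98
25,SegFormer_B2,0.50,0.25,0.25,patella,0.9521,1.7277,58
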