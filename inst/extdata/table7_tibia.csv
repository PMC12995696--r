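experiment,network,tau1,tau2,tau3,region,mean_metric_1,mean_metric_2,printed_score
2,FCN_UNet,,,,tibia,0.9665,2.4737,44
3,FCN_UNet,0.90,0.10,,tibia,0.9750,2.4756,46
3,FCN_UNet,0.50,0.50,,tibia,0.9821,7.5151,59
3,FCN_UNet,0.10,0.90,,tibia,0.9830,1.6518,92
4,FCN_UNet,0.90,,0.10,tibia,0.9644,4.1490,33
4,FCN_UNet,0.50,,0.50,tibia,0.7842,18.2342,18
4,FCN_UNet,0.10,,0.90,tibia,0.0447,207.0782,2
5,FCN_UNet,0.80,0.10,0.10,tibia,0.9774,2.0437,51
5,FCN_UNet,0.34,0.33,0.33,tibia,0.9774,6.6599,36
5,FCN_UNet,0.50,0.25,0.25,tibia,0.9802,2.0003,68
7,PSPNet_R50c,,,,tibia,0.9652,2.6144,39
8,PSPNet_R50c,0.90,0.10,,tibia,0.9799,1.7179,74
8,PSPNet_R50c,0.50,0.50,,tibia,0.9750,2.2008,48
8,PSPNet_R50c,0.10,0.90,,tibia,0.9822,1.5042,99
9,PSPNet_R50c,0.90,,0.10,tibia,0.9439,4.2554,27
9,PSPNet_R50c,0.50,,0.50,tibia,0.9126,7.3457,22
9,PSPNet_R50c,0.10,,0.90,tibia,0.4285,149.8516,10
10,PSPNet_R50c,0.80,0.10,0.10,tibia,0.9782,1.8065,62
10,PSPNet_R50c,0.34,0.33,0.33,tibia,0.9787,1.8464,60
10,PSPNet_R50c,0.50,0.25,0.25,tibia,0.9796,1.6513,75
12,DeepLabV3+_R50c,,,,tibia,0.9694,2.1484,48
13,DeepLabV3+_R50c,0.90,0.10,,tibia,0.9791,1.8058,67
13,DeepLabV3+_R50c,0.50,0.50,,tibia,0.9803,8.3346,49
13,DeepLabV3+_R50c,0.10,0.90,,tibia,0.9796,4.5917,45
14,DeepLabV3+_R50c,0.90,,0.10,tibia,0.9623,2.6777,35
14,DeepLabV3+_R50c,0.50,,0.50,tibia,0.7635,90.7169,15
14,DeepLabV3+_R50c,0.10,,0.90,tibia,0.1330,150.0556,7
15,DeepLabV3+_R50c,0.80,0.10,0.10,tibia,0.9788,1.8502,60
15,DeepLabV3+_R50c,0.34,0.33,0.33,tibia,0.9798,1.8264,69
15,DeepLabV3+_R50c,0.50,0.25,0.25,tibia,0.9813,1.5805,92
17,UPerNet_R50c,,,,tibia,0.9641,2.5798,38
18,UPerNet_R50c,0.90,0.10,,tibia,0.9802,1.6777,78
18,UPerNet_R50c,0.50,0.50,,tibia,0.9813,4.4042,58
18,UPerNet_R50c,0.10,0.90,,tibia,0.9820,1.6408,91
19,UPerNet_R50c,0.90,,0.10,tibia,0.9579,2.9166,33
19,UPerNet_R50c,0.50,,0.50,tibia,0.6780,88.4888,15
19,UPerNet_R50c,0.10,,0.90,tibia,0.3609,170.0345,6
20,UPerNet_R50c,0.80,0.10,0.10,tibia,0.9792,1.8399,64
20,UPerNet_R50c,0.34,0.33,0.33,tibia,0.9813,1.6325,87
20,UPerNet_R50c,0.50,0.25,0.25,tibia,0.9815,1.5907,92
22,SegFormer_B2,,,,tibia,0.9664,3.8379,36
23,SegFormer_B2,0.90,0.10,,tibia,0.9798,1.7162,73
23,SegFormer_B2,0.50,0.50,,tibia,0.9816,1.5509,95
23,SegFormer_B2,0.10,0.90,,tibia,0.9805,1.8588,71
24,SegFormer_B2,0.90,,0.10,tibia,0.9563,3.1591,31
24,SegFormer_B2,0.50,,0.50,tibia,0.5630,128.1249,12
24,SegFormer_B2,0.10,,0.90,tibia,0.1112,163.6501,5
25,SegFormer_B2,0.80,0.10,0.10,tibia,0.9786,2.4616,52
25,SegFormer_B2,0.34,0.33,0.33,tibia,0.9810,1.6212,87
25,SegFormer_B2,0.50,0.25,0.25,tibia,0.9800,1.8144,72
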