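experiment,network,loss,metric,mean,sd,max,min
1,FCN_UNet,CE1,iou,0.7151,0.1245,0.8918,0.1420
1,FCN_UNet,CE1,dice,0.8268,0.0992,0.9428,0.2487
1,FCN_UNet,CE1,precision,0.8561,0.1110,1.0000,0.4740
1,FCN_UNet,CE1,recall,0.8160,0.1179,0.9872,0.1424
1,FCN_UNet,CE1,hd95,27.8598,86.7608,444.0659,1.0000
1,FCN_UNet,CE1,assd,4.0110,9.6838,49.7419,0.4896
2,FCN_UNet,CE2,iou,0.7164,0.1339,0.9048,0.0924
2,FCN_UNet,CE2,dice,0.8261,0.1123,0.9500,0.1691
2,FCN_UNet,CE2,precision,0.8109,0.0991,1.0000,0.5208
2,FCN_UNet,CE2,recall,0.8676,0.1441,0.9947,0.0924
2,FCN_UNet,CE2,hd95,5.7483,8.8550,70.9151,1.0000
2,FCN_UNet,CE2,assd,1.6693,1.7163,16.7458,0.4560
6,PSPNet_R50c,CE1,iou,0.6950,0.1179,0.8868,0.3174
6,PSPNet_R50c,CE1,dice,0.8139,0.0893,0.9400,0.4819
6,PSPNet_R50c,CE1,precision,0.8048,0.1303,0.9921,0.3990
6,PSPNet_R50c,CE1,recall,0.8375,0.0884,0.9753,0.5032
6,PSPNet_R50c,CE1,hd95,4.9759,4.1895,37.0314,1.0000
6,PSPNet_R50c,CE1,assd,1.6563,0.8082,6.5322,0.5653
7,PSPNet_R50c,CE2,iou,0.7077,0.1156,0.9021,0.2482
7,PSPNet_R50c,CE2,dice,0.8229,0.0885,0.9485,0.3977
7,PSPNet_R50c,CE2,precision,0.8089,0.1060,0.9843,0.4655
7,PSPNet_R50c,CE2,recall,0.8529,0.1128,0.9919,0.2530
7,PSPNet_R50c,CE2,hd95,4.9057,6.1995,57.0313,1.0000
7,PSPNet_R50c,CE2,assd,1.5977,1.1279,10.9808,0.4438
11,DeepLabV3+_R50c,CE1,iou,0.7025,0.1175,0.9014,0.2287
11,DeepLabV3+_R50c,CE1,dice,0.8191,0.0900,0.9481,0.3722
11,DeepLabV3+_R50c,CE1,precision,0.8281,0.1129,0.9933,0.4744
11,DeepLabV3+_R50c,CE1,recall,0.8242,0.1135,0.9945,0.3050
11,DeepLabV3+_R50c,CE1,hd95,4.1198,2.5970,14.4511,1.0000
11,DeepLabV3+_R50c,CE1,assd,1.4970,0.6420,3.9733,0.4868
12,DeepLabV3+_R50c,CE2,iou,0.7211,0.1066,0.9239,0.3336
12,DeepLabV3+_R50c,CE2,dice,0.8333,0.0762,0.9604,0.5003
12,DeepLabV3+_R50c,CE2,precision,0.8064,0.1110,1.0000,0.5122
12,DeepLabV3+_R50c,CE2,recall,0.8766,0.0904,0.9946,0.4719
12,DeepLabV3+_R50c,CE2,hd95,5.7491,25.1637,424.6495,1.0000
12,DeepLabV3+_R50c,CE2,assd,1.6422,1.9367,25.4463,0.3635
16,UPerNet_R50c,CE1,iou,0.6902,0.1388,0.9039,0.0328
16,UPerNet_R50c,CE1,dice,0.8071,0.1203,0.9495,0.0635
16,UPerNet_R50c,CE1,precision,0.8407,0.1127,1.0000,0.3644
16,UPerNet_R50c,CE1,recall,0.8003,0.1500,0.9831,0.0331
16,UPerNet_R50c,CE1,hd95,4.3043,5.1317,57.1731,1.0000
16,UPerNet_R50c,CE1,assd,1.5884,1.1841,13.4316,0.4937
17,UPerNet_R50c,CE2,iou,0.7115,0.1198,0.8999,0.1667
17,UPerNet_R50c,CE2,dice,0.8249,0.0941,0.9473,0.2857
17,UPerNet_R50c,CE2,precision,0.7965,0.1116,0.9730,0.4284
17,UPerNet_R50c,CE2,recall,0.8787,0.1209,1.0000,0.1676
17,UPerNet_R50c,CE2,hd95,4.9880,3.7639,21.4009,1.0000
17,UPerNet_R50c,CE2,assd,1.5555,0.7996,5.5690,0.4845
21,SegFormer_B2,CE1,iou,0.6650,0.1351,0.8780,0.1984
21,SegFormer_B2,CE1,dice,0.7902,0.1069,0.9351,0.3311
21,SegFormer_B2,CE1,precision,0.8124,0.1490,1.0000,0.3625
21,SegFormer_B2,CE1,recall,0.7852,0.1027,0.9403,0.2227
21,SegFormer_B2,CE1,hd95,12.1648,45.1521,322.6041,1.0000
21,SegFormer_B2,CE1,assd,2.6770,5.0823,44.2741,0.4874
22,SegFormer_B2,CE2,iou,0.7214,0.1160,0.9333,0.2225
22,SegFormer_B2,CE2,dice,0.8323,0.0871,0.9655,0.3640
22,SegFormer_B2,CE2,precision,0.8096,0.1159,0.9938,0.4003
22,SegFormer_B2,CE2,recall,0.8723,0.1025,0.9958,0.2558
22,SegFormer_B2,CE2,hd95,10.3890,51.4056,447.8207,1.0000
22,SegFormer_B2,CE2,assd,2.4741,8.7994,92.9601,0.2561
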