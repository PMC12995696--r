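network,metric,printed_pp
FCN_UNet,iou,0.13
PSPNet_R50c,iou,1.27
DeepLabV3+_R50c,iou,1.86
UPerNet_R50c,iou,2.13
SegFormer_B2,iou,5.64
PSPNet_R50c,dice,0.90
DeepLabV3+_R50c,dice,1.42
UPerNet_R50c,dice,1.78
SegFormer_B2,dice,4.21
PSPNet_R50c,precision,0.41
FCN_UNet,recall,5.16
PSPNet_R50c,recall,1.54
DeepLabV3+_R50c,recall,5.24
UPerNet_R50c,recall,7.84
SegFormer_B2,recall,8.71
FCN_UNet,hd95,2211.15
PSPNet_R50c,hd95,7.02
SegFormer_B2,hd95,177.58
FCN_UNet,assd,234.17
PSPNet_R50c,assd,5.86
UPerNet_R50c,assd,3.29
SegFormer_B2,assd,20.29
all_networks,mean_metric_1,1.84
all_networks,mean_metric_2,241.35
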