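region,mean_iou,mean_dice,mean_precision,mean_recall,mean_hd95,mean_assd
patella,0.9320,0.9644,0.9733,0.9566,2.4335,0.8414
femur,0.9706,0.9851,0.9906,0.9796,2.2607,0.8111
tibia,0.9703,0.9849,0.9851,0.9848,2.3310,0.8300
patellar_tendon,0.6953,0.8147,0.7775,0.8748,4.6326,1.6412
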