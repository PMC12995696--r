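metric,printed_overall
iou,0.8921
dice,0.9373
precision,0.9316
recall,0.9490
hd95,2.9145
assd,1.0309
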