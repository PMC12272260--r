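# Cytosolic -> nuclear-localized GCaMP translation (zebrafish calcium imaging).
name: calcium
patch_size: 256
channels_a: 1
channels_b: 1
normalization: {mode: scale, hi: 99.0}   # scale-only by the 99th percentile
lambda_adv: 1
lambda_cyc: 5
lambda_info: 10
widths: [8, 16, 32]
cz: 8
batchnorm: false          # omitted: broad intra-sample dynamic range
schedule: {enabled: true, k: 10, m: 0.5}  # sigmoid growth of the cycle weight
info_loss: true
upsampler: dynamic
final_activation: linear
disc_widths: [64, 128, 256, 512]
iterations: 50000         # iteration budget is user-set for full-scale tasks
checkpoint_every: 100
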