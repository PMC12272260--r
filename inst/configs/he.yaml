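# Two-photon fluorescence -> H&E virtual staining (RGB histology).
name: he
patch_size: 512
channels_a: 1
channels_b: 3
normalization: {mode: affine, lo: 0, hi: 100}   # images scaled to [0, 1]
lambda_adv: 5
lambda_cyc: 10
lambda_info: 10
widths: [32, 64, 128, 256]
cz: 3
batchnorm: true
schedule: {enabled: false}
info_loss: true
upsampler: dynamic
final_activation: linear
disc_widths: [64, 128, 256, 512]
iterations: 50000
checkpoint_every: 100
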