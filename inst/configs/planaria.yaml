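# Low-SNR -> high-SNR restoration, planaria 64x64 z-slices.
name: planaria
patch_size: 64
channels_a: 1
channels_b: 1
normalization: {mode: affine, lo: 0.1, hi: 99.9}
lambda_adv: 1
lambda_cyc: 10
lambda_info: 1
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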