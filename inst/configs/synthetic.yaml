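# Desk-scale synthetic rings -> disks task (64x64). Loss weights follow
# the 64x64-patch restoration recipe (adv 1, cyc 10, info 1), which keeps
# the cycle term - the main anti-collapse force at short training budgets -
# dominant; architecture (channels 8/16/32, CZ 8, no batch norm) follows
# the calcium recipe, with a reduced discriminator for 64x64 frames. The
# cycle-weight schedule stays off for this task.
name: synthetic
patch_size: 64
channels_a: 1
channels_b: 1
normalization: {mode: scale, hi: 99.0}
lambda_adv: 1
lambda_cyc: 10
lambda_info: 1
widths: [8, 16, 32]
cz: 8
batchnorm: false
schedule: {enabled: false}
info_loss: true
upsampler: dynamic
final_activation: linear
disc_widths: [32, 64]
iterations: 500
checkpoint_every: 100
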