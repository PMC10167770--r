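trait,model,n_tp,accuracy
panicle_length,additive,41,0.25
panicle_length,additive,82,0.28
panicle_length,additive,122,0.28
panicle_length,additive,163,0.30
panicle_length,full,41,0.20
panicle_length,full,82,0.24
panicle_length,full,122,0.25
panicle_length,full,163,0.28
panicle_weight,additive,41,0.19
panicle_weight,additive,82,0.26
panicle_weight,additive,122,0.33
panicle_weight,additive,163,0.38
panicle_weight,full,41,0.15
panicle_weight,full,82,0.18
panicle_weight,full,122,0.21
panicle_weight,full,163,0.28
panicle_yield,additive,41,0.08
panicle_yield,additive,82,0.12
panicle_yield,additive,122,0.17
panicle_yield,additive,163,0.22
panicle_yield,full,41,0.09
panicle_yield,full,82,0.15
panicle_yield,full,122,0.17
panicle_yield,full,163,0.27
kernel_number,additive,41,0.18
kernel_number,additive,82,0.26
kernel_number,additive,122,0.29
kernel_number,additive,163,0.34
kernel_number,full,41,0.17
kernel_number,full,82,0.22
kernel_number,full,122,0.24
kernel_number,full,163,0.29
thousand_kernel_weight,additive,41,0.01
thousand_kernel_weight,additive,82,0.02
thousand_kernel_weight,additive,122,0.04
thousand_kernel_weight,additive,163,0.12
thousand_kernel_weight,full,41,0.03
thousand_kernel_weight,full,82,0.02
thousand_kernel_weight,full,122,0.02
thousand_kernel_weight,full,163,0.18
days_to_flowering,additive,41,0.09
days_to_flowering,additive,82,0.12
days_to_flowering,additive,122,0.14
days_to_flowering,additive,163,0.23
days_to_flowering,full,41,0.06
days_to_flowering,full,82,0.10
days_to_flowering,full,122,0.13
days_to_flowering,full,163,0.14
plant_height,additive,41,0.23
plant_height,additive,82,0.28
plant_height,additive,122,0.33
plant_height,additive,163,0.38
plant_height,full,41,0.26
plant_height,full,82,0.30
plant_height,full,122,0.33
plant_height,full,163,0.34
grain_yield,additive,41,0.46
grain_yield,additive,82,0.53
grain_yield,additive,122,0.56
grain_yield,additive,163,0.59
grain_yield,full,41,0.49
grain_yield,full,82,0.52
grain_yield,full,122,0.56
grain_yield,full,163,0.58
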