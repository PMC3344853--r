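# Pooled-sequencing simulation: study-design defaults.
# Two pools of 10 diploid full-sib fish at ~0.97X coverage per fish;
# candidate-site mixture of true SNPs, paralog artifacts and monomorphic
# sites; Illumina-like base error and quality model.
n_sites: 10000
prop_true_snp: 0.03
prop_paralog: 0.01
n_fish_per_pool: 10
coverage_per_fish: 0.97
error_rate: 0.01
qual_mean: 35
qual_sd: 5
beta_shape1: 0.5
beta_shape2: 0.5
paralog_alt_fraction: 0.5
paralog_depth_multiplier: 2
dh_detection_rate: 0.5
family_mode: false
seed: 1
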