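# Demo configuration for run_full() on the bundled synthetic fixture.
# The fixture (synthetic_counts.tsv / synthetic_metadata.tsv) is a small
# simulated two-genotype cohort generated by synth_community(); resampling
# counts are reduced accordingly. 'table', 'metadata' and 'out_dir' are
# supplied as overrides by the caller.
group_a: "+/+"
group_b: "+/R258W"
dialect: biom_tsv
rarefy_depth: 1500
rarefy_perms: 20
key_threshold: 0.10
prevalence: 0.40
p_max: 0.05
r_min: 0.7
network_perms: 60
sparcc_iter: 10
perm_sparcc_iter: 3
n_boot: 200
cv: loocv
variance_target: 0.80
seed: 1
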