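# Demonstration pipeline run on synthetic data: all stages, small sizes.
stages: [simulate, equilibrium, tracer, assay, phenotype]
seed: 1
n_replicates: 4
n_per_group: 8
n_per_arm: 4
log_level: quiet
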