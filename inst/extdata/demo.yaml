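# Demo configuration for runPipeline(): simulates an aging cohort at the
# package's reference scale (600 training / 550 test subjects, 264 regional
# features), trains the brain-age model, applies the age-bias correction,
# decodes per-feature mutual information and compares sex subgroups.
# Copy, set outDir, and run:
#   runPipeline("demo.yaml")
outDir: brainage_demo_run
seed: 42
nTrain: 600
nTest: 550
k: 3
grid: [0.1, 1, 10, 100]
epsilon: 0.1
units: nats
combineVolumes: false
subgroup: true
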