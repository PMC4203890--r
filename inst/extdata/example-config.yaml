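# Example pipeline configuration; keys mirror pipelineConfig() arguments.
tumorCounts: tumor_counts.tsv
normalCounts: normal_counts.tsv
somaticVariants: somatic.vcf
outDir: results
unitKind: scna
seed: 1
hetBand: 0.2
minMarkers: 5
alpha: 0.01
window: 5
maxNt: 6
thresholdMultiplier: 2
threshold: 0.95
minDepth: 20
minSaf: 0.05
minValue: 0.05
minBins: 50
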