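# Bundled demonstration run: a fully synthetic two-condition study with
# planted ground truth, scaled so the whole pipeline finishes in well under
# ten minutes on one CPU.
synthetic:
  nGenes: 600
  nDatasetsPerCondition: 2
  nSamplesPerGroup: 10
  effectSize: 2.0
  degFraction: 0.2
  nModulesPerCondition: 3
  moduleSizeRange: [8, 12]
  intraModuleEdgeProb: 0.9
  backgroundEdgeProb: 0.015
  nPlantedCrosstalkPairs: 2
  crosstalkEdgesPerPair: 24
  nRegulatorsPerClass: 10
  targetsPerRegulator: 20
  nPlantedPivots: 4
  rngSeed: 101
conditions: [UC, CRC]
fdrCutoff: 0.05
nPermutations: 200
R: 200
swapsPerEdge: 10
alpha: 0.05
pivotAlpha: 0.05
minTargets: 2
seed: 101
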