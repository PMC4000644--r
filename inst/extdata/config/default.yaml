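# Reference synthetic run: four-group expression study with a planted
# start-to-end path whose nodes carry the regression signal.
mode: synthetic
seed: 7
alpha: 0.05
anova_mode: retain
lambda2_grid: [0, 0.5, 2]
n_folds: 10
ilp_lambda: 0.65
simulation:
  nPerGroup: 8
  nGenes: 60
  nSupport: 5
  effectSize: 2
  pathLength: 3
  pathCorrelation: 0.9
  noiseSd: 1
  networkModel: preferential-attachment
  attachmentEdges: 2
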