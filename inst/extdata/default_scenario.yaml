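# Default synthetic-registry scenario: a hereditary breast-ovarian cancer
# registry of 1600 families ascertained through an affected, genotyped
# proband, with partial genotyping of first-degree relatives.
q: 0.02
n_families: 1600
gamma: 0.3
seed: 20180202
gene: BRCA1
F_breast_70:
  carrier: 0.50
  noncarrier: 0.16
F_ovarian_70:
  carrier: 0.215
  noncarrier: 0.014
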