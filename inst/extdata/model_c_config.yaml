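model: C
'N': 5000
total_generations: 100
admixture_generation: 30
n_accepted: 1000
seed: 1
observed:
- label: Indo-European
  'n': 2677
  carriers: 0
  role: indo_european
- label: Hungarian Sekler
  'n': 95
  carriers: 4
  role: sekler
- label: Ural-Siberian
  'n': 957
  carriers: 124
  role: ural_siberian
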