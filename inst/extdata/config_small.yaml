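# Small end-to-end pipeline preset: simulate -> validate -> abundance ->
# stats -> ordination -> rf -> lsa, a few seconds on one CPU.
seed: 1
simulate:
  preset: small
abundance:
  rank: family
ordination:
  n_perm: 199
rf:
  n_trees: 301
  n_splits: 10
  n_null_perms: 0
  mtry: 4
lsa:
  D: 2
  n_perm: 199
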