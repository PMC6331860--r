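# Example synthetic-benchmark specification for `sqbvs.R simulate`.
#
# Each activity class is built around `core_size` fragments private to the
# class; an active carries each core fragment with probability `core_prob`
# (higher -> more homogeneous class, i.e. higher mean pairwise Tanimoto).
# All compounds additionally carry background fragments: every fragment of
# the universe is included with probability `background_rate`.  Drawn
# fragments get a count of 1 + Poisson(count_dispersion).
fragment_universe: 512
background_rate: 0.02
count_dispersion: 0.5
n_decoys: 1600
seed: 42            # overridden by --seed when given
classes:
  - class_id: HOM1  # homogeneous class, diversity ~0.3
    n_actives: 40
    core_size: 30
    core_prob: 0.85
  - class_id: HET1  # heterogeneous class, diversity ~0.1
    n_actives: 40
    core_size: 80
    core_prob: 0.25
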