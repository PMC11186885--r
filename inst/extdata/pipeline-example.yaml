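# Example pipeline configuration: simulate a 2,000-participant cohort
# across 25 centers and run both analysis parts.
generator:
  n: 2000
  n_centers: 25
  seed: 20140101
split_year: 2019
part1: true
part2: true
multilevel: false
outcomes: [dementia, clinical_ad, ppa, bvftd, hs_a, adnc, lewy]
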