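seed: 20230220
n_sorties: 17
animals_per_sortie: 23.0
sortie_sizes:
- 20
- 25
- 24
- 25
- 25
- 25
- 20
- 24
- 25
- 20
- 24
- 23
- 19
- 25
- 23
- 24
- 19
ct_lognormal:
  meanlog: 4.0943446
  sdlog: 0.8
tti_rate_per_ammo:
  RIFLE_308: 0.0855924
  BUCK_00: 0.063739
  BUCK_1: 0.0696682
  BUCK_4: 0.0748933
censor_prob: 0.23
pellet_hit_prob: 0.22
zone_weights:
  HEAD: 0.08
  NECK: 0.12
  THORAX: 0.55
  ABDOMEN: 0.15
  LIMBS: 0.1
thorax_concentration:
  BUCK_00: 3.0
  BUCK_1: 2.0
  BUCK_4: 1.4
shots_mean: 2.3
insitu_fraction: 0.2
exsitu_fraction: 0.15
sex_age_probs:
  ADULT_M: 0.68
  ADULT_F: 0.17
  YEARLING: 0.1
  FAWN: 0.05
mass_lognormal:
  meanlog: 4.1271344
  sdlog: 0.35
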