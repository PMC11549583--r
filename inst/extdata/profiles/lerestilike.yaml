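# "lerestilike" generator profile (SYNTHETIC): emulates the published
# marginals of a rural Romanian personal-network vaccination study; it
# encodes no individual-level data. Coefficients are log odds ratios.
n_egos: 83
alters_range: [15, 16, 17, 18, 19, 20, 21, 22, 23, 24, 25]
alters_weights: [1, 1, 1, 1, 1, 3, 3, 5, 5, 20, 60]
target_density: 0.65
density_sd: 0.21
ego:
  age_mean: 53.33
  age_sd: 15.86
  p_female: 0.52
  educ_mean: 9.70
  educ_sd: 1.78
  p_single: 0.125
  p_employed: 0.5625
  p_vaccinated: 0.78
alter:
  age_mean: 52.64
  age_sd: 16.06
  p_female: 0.525
  educ_mean: 9.35
  educ_sd: 1.93
  p_single: 0.204
  closeness_probs:
    not_at_all: 0.05
    not_very: 0.15
    close: 0.40
    very_close: 0.40
  meet_probs:
    lt_once_year: 0.02
    once_year: 0.05
    few_times_year: 0.18
    once_month: 0.20
    every_2_weeks: 0.20
    weekly: 0.20
    daily: 0.15
media_probs:
  traditional: 0.17
  online: 0.33
  both: 0.45
p_media_missing: 0.05
coefficients:
  alter_sex: 0.1222176
  alter_education: 0.6259384
  alter_single: -0.4004776
  alter_age: -0.0202027
  intensity: -0.0833816
  ego_sex: 0.0392207
  ego_education: 0.2151114
  ego_age: 0.0198026
  ego_employed: -0.4620355
  ego_vaccinated: 1.3217558
  media_online: -0.9942523
  media_both: -0.2876821
  size: -0.0408220
  density: 0.2070142
  components: 0.0392207
intercept: 0.5753641
sigma_ego: 0.913
contagion_rounds: 1
contagion_strength: 1.0
p_isolate: 0.01
p_missing_alter_vacc: 0.113
referral:
  n_seeds: 6
  p_concordant: 0.76
  refusal_rate: 0.458
  mean_referrals: 2
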