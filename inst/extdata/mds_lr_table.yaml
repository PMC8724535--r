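# Likelihood-ratio table for the MDS research-criteria prodromal-PD calculator.
#
# Values populated from the 2019 update of the MDS research criteria for
# prodromal Parkinson's disease (Heinzel et al., Mov Disord 2019). The table is
# deliberately editable: swap in your own LR+/LR- values or age priors without
# touching code. lr_positive applies when a marker is present, lr_negative when
# it is absent; markers in state "missing" always contribute 1.0.
#
# Age priors are the pretest probability of prodromal PD for half-open age
# bands [min, max).
version: "2019-mds-defaults"
age_priors:
  - {age_min: 50, age_max: 55, prior: 0.004}
  - {age_min: 55, age_max: 60, prior: 0.0075}
  - {age_min: 60, age_max: 65, prior: 0.0125}
  - {age_min: 65, age_max: 70, prior: 0.02}
  - {age_min: 70, age_max: 75, prior: 0.025}
  - {age_min: 75, age_max: 80, prior: 0.035}
  - {age_min: 80, age_max: .inf, prior: 0.04}
markers:
  # -- risk markers --
  - {name: male_sex,                            class: risk,      lr_positive: 1.2,  lr_negative: 0.8}
  - {name: pesticide_exposure,                  class: risk,      lr_positive: 1.5,  lr_negative: 1.0}
  - {name: non_use_of_caffeine,                 class: risk,      lr_positive: 1.35, lr_negative: 0.88}
  - {name: non_smoking,                         class: risk,      lr_positive: 1.25, lr_negative: 0.45}
  - {name: first_degree_relative_pd,            class: risk,      lr_positive: 2.5,  lr_negative: 1.0}
  - {name: dm2,                                 class: risk,      lr_positive: 1.5,  lr_negative: 1.0}
  - {name: physical_inactivity,                 class: risk,      lr_positive: 1.3,  lr_negative: 0.9}
  # -- prodromal markers --
  - {name: possible_rbd,                        class: prodromal, lr_positive: 2.8,  lr_negative: 0.89}
  - {name: subthreshold_parkinsonism,           class: prodromal, lr_positive: 10.0, lr_negative: 0.7}
  - {name: constipation,                        class: prodromal, lr_positive: 2.5,  lr_negative: 0.82}
  - {name: excessive_daytime_somnolence,        class: prodromal, lr_positive: 2.7,  lr_negative: 0.86}
  - {name: symptomatic_orthostatic_hypotension, class: prodromal, lr_positive: 3.2,  lr_negative: 0.8}
  - {name: erectile_dysfunction,                class: prodromal, lr_positive: 3.4,  lr_negative: 0.87}
  - {name: urinary_dysfunction,                 class: prodromal, lr_positive: 2.0,  lr_negative: 0.9}
  - {name: depression_anxiety,                  class: prodromal, lr_positive: 1.6,  lr_negative: 0.88}
  - {name: global_cognitive_deficit,            class: prodromal, lr_positive: 1.8,  lr_negative: 0.88}
# LRs substituted for a marker when the top quartile of the polygenic risk
# score is used as a risk marker (sensitivity analysis): Q4 -> 1.57,
# Q2/Q3 -> 1.00, Q1 -> 0.45.
prs_quartile_scheme: {Q1: 0.45, Q2: 1.0, Q3: 1.0, Q4: 1.57}
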