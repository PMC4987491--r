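generator:
  n_sites: 10
  element_marginals:
    name: 0.93
    street_address: 0.83
    funding_sources: 0.44
    purpose_mission: 0.79
    uses_limitations: 0.82
    commercial_association: 0.71
    identify_advertising: 0.4666667
    editorial_policy: 0.39
    authorship: 0.38
    privacy_policy: 0.96
    personal_info_protection: 0.83
    feedback_mechanism: 0.9
    user_info_use: 0.5
    date_created: 0.25
    date_reviewed: 0.28
    copyright_date: 0.5
  na_probability:
    identify_advertising: 0.4
  latent_correlation: 0.3
  principle_quality_mean:
  - 3.4
  - 3.4
  - 3.4
  - 3.4
  - 3.4
  - 3.4
  - 3.4
  - 3.4
  - 3.4
  - 3.4
  - 3.4
  - 3.4
  - 3.4
  - 3.4
  - 3.4
  - 3.4
  - 3.4
  - 3.4
  - 3.4
  principle_quality_sd:
  - 0.5
  - 0.5
  - 0.5
  - 0.5
  - 0.5
  - 0.5
  - 0.5
  - 0.5
  - 0.5
  - 0.5
  - 0.5
  - 0.5
  - 0.5
  - 0.5
  - 0.5
  - 0.5
  - 0.5
  - 0.5
  - 0.5
  rating_noise_sd: 0.5
  rating_cutpoints:
  - 1.5
  - 2.5
  - 3.5
  rater_agreement: 0.9
  sponsor_mix:
    for-profit: 0.48
    nonprofit: 0.36
    government: 0.16
  seed: 42
seed: 42
two_rater: yes
package_version: 0.1.0
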