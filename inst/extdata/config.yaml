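# Demonstration run configuration for the bundled clinic.csv sample.
attributes:
  - {name: age, role: quasi_identifier, hierarchy: hierarchy_age.csv}
  - {name: sex, role: quasi_identifier, hierarchy: hierarchy_sex.csv}
  - {name: zip, role: quasi_identifier, hierarchy: hierarchy_zip.csv}
  - {name: diagnosis, role: sensitive}
models:
  - {type: k_anonymity, k: 4}
  - {type: t_closeness, t: 0.35, sensitive: diagnosis, variant: equal}
transformation: global
suppression_limit: 1.0
partitions: 2
harmonization: average
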