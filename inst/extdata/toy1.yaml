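exposure: a
outcome: 'y'
mediators:
- m
covariates: []
nodes:
- name: a
  parents: []
  levels:
  - 0.0
  - 1.0
  cpt:
  - prob:
    - 0.5
    - 0.5
- name: m
  parents:
  - a
  levels:
  - 0.0
  - 1.0
  cpt:
  - a: 0.0
    prob:
    - 0.8
    - 0.2
  - a: 1.0
    prob:
    - 0.2
    - 0.8
- name: 'y'
  parents:
  - a
  - m
  levels:
  - 0.0
  - 1.0
  cpt:
  - a: 0.0
    m: 0.0
    prob:
    - 0.9
    - 0.1
  - a: 1.0
    m: 0.0
    prob:
    - 0.6
    - 0.4
  - a: 0.0
    m: 1.0
    prob:
    - 0.5
    - 0.5
  - a: 1.0
    m: 1.0
    prob:
    - 0.2
    - 0.8
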