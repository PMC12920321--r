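size_map:
  S: 1
  M: 2
  L: 3
  XL: 4
operating_rooms:
- OR1
- OR2
or_day_window:
- 480.0
- 960.0
outpatient_rate: 2.0
outpatient_window:
- 480.0
- 1020.0
tray_types:
- id: A
  size_class: M
  compat_class: regular
  current_inventory: 6
  source: surgical
- id: B
  size_class: L
  compat_class: regular
  current_inventory: 8
  source: surgical
- id: C
  size_class: S
  compat_class: regular
  current_inventory: 4
  source: outpatient
surgery_types:
- id: hernia
  duration_mu: 4.041664304393
  duration_sigma: 0.324592845975
  rates:
    Mon: 3.0
    Tue: 3.0
    Wed: 3.0
    Thu: 3.0
    Fri: 3.0
    Sat: 1.0
    Sun: 1.0
  configurations:
  - probability: 0.6
    trays:
      A: 1
  - probability: 0.4
    trays:
      B: 1
- id: ortho
  duration_mu: 4.447129412501
  duration_sigma: 0.324592845975
  rates:
    Mon: 2.0
    Tue: 2.0
    Wed: 2.0
    Thu: 2.0
    Fri: 2.0
    Sat: 0.5
    Sun: 0.5
  configurations:
  - probability: 0.7
    trays:
      A: 1
      B: 1
  - probability: 0.3
    trays:
      B: 2
workstations:
- kind: pre_clean
  count: 1
  capacity: 1
  service_mu: -0.111571775657
  service_sigma: 0.472380727077
- kind: assemble
  count: 1
  capacity: 1
  service_mu: 0.581575404903
  service_sigma: 0.472380727077
- kind: wrap
  count: 1
  capacity: 1
  service_mu: -0.767357183119
  service_sigma: 0.38525317016
machines:
- kind: disinfector
  count: 1
  capacity: 8
  layers: 2
  layer_units: 4
  charge_minutes: 30.0
  load_mu: -0.043088848121
  load_sigma: 0.293560379209
  unload_mu: -0.767357183119
  unload_sigma: 0.38525317016
  start_threshold: 0.25
- kind: autoclave
  count: 1
  capacity: 4
  charge_minutes: 30.0
  load_mu: -0.043088848121
  load_sigma: 0.293560379209
  start_threshold: 0.5
staff:
- team: pre_cleaning
  days:
  - Mon
  - Tue
  - Wed
  - Thu
  - Fri
  - Sat
  - Sun
  start: 420.0
  end: 1080.0
  headcount: 2
- team: post_cleaning
  days:
  - Mon
  - Tue
  - Wed
  - Thu
  - Fri
  - Sat
  - Sun
  start: 420.0
  end: 1080.0
  headcount: 2
batch_schedule:
  insertion_times:
  - 660.0
  - 960.0
  batched_sources:
  - outpatient

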