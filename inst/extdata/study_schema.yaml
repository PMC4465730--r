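# Default study configuration: eleven health-system performance domains,
# each with positive / no_change / negative outcome levels. Ranks give the
# a-priori expected importance ordering used to build the design prior.
attributes:
  - id: effectiveness_safety
    name: Clinical effectiveness and patient safety
    rank: 1
    levels: [positive, no_change, negative]
  - id: best_practice
    name: Best practice service use
    rank: 2
    levels: [positive, no_change, negative]
  - id: care_equity
    name: Care equity
    rank: 3
    levels: [positive, no_change, negative]
  - id: coordination
    name: Care coordination, teamwork and continuity
    rank: 4
    levels: [positive, no_change, negative]
  - id: patient_centeredness
    name: Patient centeredness
    rank: 5
    levels: [positive, no_change, negative]
  - id: timeliness
    name: Timeliness
    rank: 6
    levels: [positive, no_change, negative]
  - id: short_term_cost
    name: Short term cost containment and budget safety
    rank: 7
    levels: [positive, no_change, negative]
  - id: long_term_cost
    name: Long term cost containment and budget safety
    rank: 8
    levels: [positive, no_change, negative]
  - id: provider_wellness
    name: Provider wellness
    rank: 9
    levels: [positive, no_change, negative]
  - id: innovation
    name: Innovation
    rank: 10
    levels: [positive, no_change, negative]
  - id: gaming
    name: Gaming the system
    rank: 11
    levels: [positive, no_change, negative]
reference:
  attribute: effectiveness_safety
  level: negative
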