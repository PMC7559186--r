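# Default riskwarn project configuration.
#
# The hierarchy is the three-level meat-processing risk index system:
# target A, first-level B1-B3, twelve leaf indicators u1-u12.
#
# Hazard warning ladders below are PLACEHOLDERS on plausible measurement
# scales. The real five-level cut-offs must be taken from the regulatory
# limits applicable to your products and jurisdiction (veterinary drug MRLs,
# pesticide MRLs, heavy-metal limits, microbiological criteria, metal
# detection standards) and edited in before production use.
hierarchy:
  nodes:
    - {id: A, label: Risk of food quality safety}
    - {id: B1, parent: A, label: External environmental risk}
    - {id: B2, parent: A, label: Internal environmental risk}
    - {id: B3, parent: A, label: Risk of consumers concern}
    - {id: u1, parent: B1, label: Policy adjustment risk}
    - {id: u2, parent: B1, label: Economic environment risk}
    - {id: u3, parent: B1, label: Natural disasters and climate impacts}
    - {id: u4, parent: B1, label: Source hazards of raw materials}
    - {id: u5, parent: B2, label: Insufficiency of top management responsibility}
    - {id: u6, parent: B2, label: Personnel management risk}
    - {id: u7, parent: B2, label: Hazard control risk}
    - {id: u8, parent: B2, label: Product innovation risk}
    - {id: u9, parent: B3, label: Concerned about the harmful substances}
    - {id: u10, parent: B3, label: Concerned about counterfeiting}
    - {id: u11, parent: B3, label: Concerns about sensory quality}
    - {id: u12, parent: B3, label: Concerns about the environment}
hazards:
  - {id: doxycycline, unit: ug/kg, cutoffs: [20, 50, 100, 200, 400]}
  - {id: enrofloxacin, unit: ug/kg, cutoffs: [10, 30, 100, 200, 400]}
  - {id: chlorpyrifos, unit: mg/kg, cutoffs: [0.01, 0.02, 0.05, 0.1, 0.2]}
  - {id: flumetasone, unit: mg/kg, cutoffs: [0.01, 0.02, 0.05, 0.1, 0.2]}
  - {id: nitrite, unit: mg/kg, cutoffs: [1, 3, 10, 30, 70]}
  - {id: mercury, unit: mg/kg, cutoffs: [0.005, 0.01, 0.02, 0.05, 0.1]}
  - {id: cadmium, unit: mg/kg, cutoffs: [0.01, 0.02, 0.05, 0.1, 0.2]}
  - {id: lead, unit: mg/kg, cutoffs: [0.02, 0.05, 0.1, 0.2, 0.5]}
  - {id: colony_count, unit: CFU/g, cutoffs: [1000, 10000, 50000, 100000, 500000]}
  - {id: coliform, unit: MPN/100g, cutoffs: [30, 90, 300, 1000, 3000]}
  - {id: iron, unit: mm, cutoffs: [0.5, 0.8, 1.2, 1.5, 2.0]}
  - {id: sus, unit: mm, cutoffs: [0.8, 1.2, 1.8, 2.5, 3.0]}
options:
  questionnaire_scale_factor: 10
  cr_threshold: 0.1
  detection_leaves: u7
  fit:
    families: [betageneral, normal, lognormal, gamma, weibull, triangular, uniform]
    bins: 33
    alpha: 0.05
    min_expected: 5
  simulate:
    n: 10000
    seed: 42
    mode: latin_hypercube
    bins: [0, 10, 20, 30, 40, 50, 60, 70, 100]
    thresholds: [40, 70]
  sensitivity:
    method: rank
    scenario_threshold: 40
    shift_cutoff: 0.5
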