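# Default linguistic-variable configuration for the twelve soil parameters.
#
# Families follow the published assignment: triangular for pH and EC,
# trapezoidal for OC and N, rational (exponential-like) decay for P, S/Z
# shoulders for K, Gaussian for the six micronutrients. Term breakpoints are
# NOT published; the defaults below encode common Indian soil-fertility
# rating conventions (e.g. OC low < 0.5 %, medium 0.5-0.75 %, high > 0.75 %;
# available N low < 280 kg/ha; USDA salinity classes for ECe) and are fully
# overridable: pass your own file to read_soil_variables().
#
# level indices are the antecedent-vector slot values of the rule base.
variables:
  - name: "pH"
    units: "-"
    domain: [0, 14]
    terms:
      - {label: Excessive-Acid, level: 1, family: triangular, alpha_min: 0, beta: 0, alpha_max: 5}
      - {label: Acid,           level: 2, family: triangular, alpha_min: 4, beta: 5.5, alpha_max: 7}
      - {label: Neutral,        level: 3, family: triangular, alpha_min: 6, beta: 7, alpha_max: 8.3}
      - {label: Alkaline,       level: 4, family: triangular, alpha_min: 7.5, beta: 14, alpha_max: 14}
  - name: "EC"
    units: dS/m
    domain: [0, 20]
    terms:
      - {label: Non-saline,        level: 1, family: triangular, alpha_min: 0, beta: 0, alpha_max: 2.5}
      - {label: Slightly-Saline,   level: 2, family: triangular, alpha_min: 1.5, beta: 3, alpha_max: 4.5}
      - {label: Moderately-Saline, level: 3, family: triangular, alpha_min: 3.5, beta: 6, alpha_max: 8.5}
      - {label: Strongly-Saline,   level: 4, family: triangular, alpha_min: 7.5, beta: 20, alpha_max: 20}
  - name: "OC"
    units: "%"
    domain: [0, 3]
    terms:
      - {label: Low,       level: 1, family: trapezoidal, alpha_min: 0, beta1: 0, beta2: 0.4, alpha_max: 0.55}
      - {label: Medium,    level: 2, family: trapezoidal, alpha_min: 0.4, beta1: 0.55, beta2: 0.7, alpha_max: 0.8}
      - {label: High,      level: 3, family: trapezoidal, alpha_min: 0.7, beta1: 0.8, beta2: 1.0, alpha_max: 1.2}
      - {label: Very-high, level: 4, family: trapezoidal, alpha_min: 1.0, beta1: 1.2, beta2: 3, alpha_max: 3}
  - name: "N"
    units: kg/ha
    domain: [0, 1000]
    terms:
      - {label: Low,        level: 1, family: trapezoidal, alpha_min: 0, beta1: 0, beta2: 240, alpha_max: 320}
      - {label: Sufficient, level: 2, family: trapezoidal, alpha_min: 240, beta1: 320, beta2: 500, alpha_max: 600}
      - {label: High,       level: 3, family: trapezoidal, alpha_min: 500, beta1: 600, beta2: 1000, alpha_max: 1000}
  - name: "P"
    units: kg/ha
    domain: [0, 150]
    terms:
      - {label: Low,        level: 1, family: exponential_like, beta: 10, gamma: 0.004444}
      - {label: Sufficient, level: 2, family: exponential_like, beta: 40, gamma: 0.004444}
      - {label: High,       level: 3, family: exponential_like, beta: 70, gamma: 0.004444}
  - name: "K"
    units: kg/ha
    domain: [0, 1000]
    terms:
      - {label: Low,        level: 1, family: s_shape, alpha_min: 100, alpha_max: 160, invert: true}
      - {label: Sufficient, level: 2, family: trapezoidal, alpha_min: 100, beta1: 160, beta2: 240, alpha_max: 320}
      - {label: High,       level: 3, family: s_shape, alpha_min: 240, alpha_max: 320}
  - name: "S"
    units: mg/kg
    domain: [0, 100]
    terms:
      - {label: Low,    level: 1, family: gaussian, beta: 5, alpha_g: 0.03125}
      - {label: Medium, level: 2, family: gaussian, beta: 15, alpha_g: 0.02}
      - {label: High,   level: 3, family: gaussian, beta: 25, alpha_g: 0.02}
  - name: "Fe"
    units: mg/kg
    domain: [0, 50]
    terms:
      - {label: Low,    level: 1, family: gaussian, beta: 2, alpha_g: 0.2222}
      - {label: Medium, level: 2, family: gaussian, beta: 6, alpha_g: 0.125}
      - {label: High,   level: 3, family: gaussian, beta: 12, alpha_g: 0.0556}
  - name: "Mn"
    units: mg/kg
    domain: [0, 20]
    terms:
      - {label: Low,    level: 1, family: gaussian, beta: 1, alpha_g: 0.8889}
      - {label: Medium, level: 2, family: gaussian, beta: 3, alpha_g: 0.5}
      - {label: High,   level: 3, family: gaussian, beta: 6, alpha_g: 0.2222}
  - name: "Zn"
    units: mg/kg
    domain: [0, 10]
    terms:
      - {label: Low,    level: 1, family: gaussian, beta: 0.3, alpha_g: 12.5}
      - {label: Medium, level: 2, family: gaussian, beta: 0.9, alpha_g: 5.5556}
      - {label: High,   level: 3, family: gaussian, beta: 1.8, alpha_g: 2.4691}
  - name: "B"
    units: mg/kg
    domain: [0, 5]
    terms:
      - {label: Low,    level: 1, family: gaussian, beta: 0.25, alpha_g: 22.222}
      - {label: Medium, level: 2, family: gaussian, beta: 0.75, alpha_g: 8}
      - {label: High,   level: 3, family: gaussian, beta: 1.5, alpha_g: 3.125}
  - name: "Cu"
    units: mg/kg
    domain: [0, 10]
    terms:
      - {label: Low,    level: 1, family: gaussian, beta: 0.1, alpha_g: 22.222}
      - {label: Medium, level: 2, family: gaussian, beta: 0.4, alpha_g: 12.5}
      - {label: High,   level: 3, family: gaussian, beta: 1.0, alpha_g: 4.0816}
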