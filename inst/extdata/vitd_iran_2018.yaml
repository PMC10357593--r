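# School-based vitamin D supplementation vs. no intervention for
# adolescent depression prevention; Iran, 2018 USD, one-year horizon.
#
# Probabilities are fixed (no uncertainty distribution); costs are Gamma
# and utilities Beta, each specified as mean and SD and fitted by method
# of moments. Post-supplementation sufficiency is the complement of
# deficiency (0.828 = 1 - 0.172).
name: vitd_iran_2018
description: >
  Two-strategy decision tree for a national vitamin D supplementation
  program in adolescents (11-18 y): vitamin D status (deficient /
  sufficient) followed by depression incidence conditional on status.
intervention: Vitamin D Supplementation
comparator: No Intervention

parameters:
  cost_depression:
    role: cost
    family: gamma
    mean: 335.4
    sd: 35
    units: USD
  cost_supplement:
    role: cost
    family: gamma
    mean: 0.604
    sd: 0.120
    units: USD
  utility_healthy:
    role: utility
    family: beta
    mean: 0.760
    sd: 0.070
  utility_depressed:
    role: utility
    family: beta
    mean: 0.545
    sd: 0.035
  p_deficient_pre:
    role: probability
    value: 0.76
  p_sufficient_pre:
    role: probability
    value: 0.24
  p_deficient_post:
    role: probability
    value: 0.172
  p_sufficient_post:
    role: probability
    value: 0.828
  p_depression_deficient:
    role: probability
    value: 0.314
  p_depression_sufficient:
    role: probability
    value: 0.16

strategies:
  - name: No Intervention
    upfront_cost: 0
    root:
      label: vitamin D status
      branches:
        - p: p_deficient_pre
          node:
            label: depression incidence (deficient)
            branches:
              - p: p_depression_deficient
                node:
                  cost: cost_depression
                  utility: utility_depressed
                  outcome: depression
              - p: 0.686
                node:
                  cost: 0
                  utility: utility_healthy
                  outcome: healthy
        - p: p_sufficient_pre
          node:
            label: depression incidence (sufficient)
            branches:
              - p: p_depression_sufficient
                node:
                  cost: cost_depression
                  utility: utility_depressed
                  outcome: depression
              - p: 0.84
                node:
                  cost: 0
                  utility: utility_healthy
                  outcome: healthy
  - name: Vitamin D Supplementation
    upfront_cost: cost_supplement
    root:
      label: vitamin D status
      branches:
        - p: p_deficient_post
          node:
            label: depression incidence (deficient)
            branches:
              - p: p_depression_deficient
                node:
                  cost: cost_depression
                  utility: utility_depressed
                  outcome: depression
              - p: 0.686
                node:
                  cost: 0
                  utility: utility_healthy
                  outcome: healthy
        - p: p_sufficient_post
          node:
            label: depression incidence (sufficient)
            branches:
              - p: p_depression_sufficient
                node:
                  cost: cost_depression
                  utility: utility_depressed
                  outcome: depression
              - p: 0.84
                node:
                  cost: 0
                  utility: utility_healthy
                  outcome: healthy
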