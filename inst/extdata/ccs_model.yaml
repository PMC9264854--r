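# Path-diagram configuration of the cervical-cancer screening model:
# binary screening outcome, three mediators (contraception use, number of
# children, STI awareness), schooling continuous, all other variables
# categorical with the stated reference levels.
variables:
  - name: screening
    role: outcome
    family: bernoulli
    levels: [not_screened, screened]
    reference: not_screened
  - name: age
    role: covariate
    family: bernoulli
    levels: ["15-34", "35-49"]
    reference: "15-34"
  - name: bmi
    role: covariate
    family: multinomial
    levels: [underweight, normal, overweight, obese]
    reference: underweight
  - name: facility
    role: covariate
    family: multinomial
    levels: [not_a_big_problem, distance_only, transport_only, distance_and_transport]
    reference: not_a_big_problem
  - name: contraception
    role: mediator
    family: multinomial
    levels: [none, condom, others]
    reference: none
  - name: children
    role: mediator
    family: multinomial
    levels: [none, one_or_two, three_or_four, more_than_four]
    reference: none
  - name: autonomy
    role: covariate
    family: multinomial
    levels: [alone, with_husband, husband_or_family]
    reference: alone
  - name: sex_partners
    role: covariate
    family: multinomial
    levels: [one, two, more_than_two]
    reference: one
  - name: sti
    role: mediator
    family: bernoulli
    levels: ["no", "yes"]
    reference: "no"
  - name: schooling
    role: covariate
    family: continuous
  - name: religion
    role: covariate
    family: multinomial
    levels: [hindu, muslim, christian, others]
    reference: hindu
  - name: wealth
    role: covariate
    family: multinomial
    levels: [poorest, poorer, middle, richer, richest]
    reference: poorest
equations:
  - response: screening
    predictors: [age, bmi, facility, contraception, children, autonomy,
                 sex_partners, sti, schooling, religion, wealth]
  - response: contraception
    predictors: [religion, schooling]
  - response: children
    predictors: [wealth, religion]
  - response: sti
    predictors: [schooling]
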