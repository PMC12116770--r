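# Small smoke-test generator configuration: same structure as the calibrated
# config but tiny, with fixed documentation prevalence and short notes, for
# fast end-to-end runs.
n_patients: 60
date_window:
  start: "2016-01-01"
  end: "2022-02-28"
documentation:
  mode: fixed
  prevalence: 0.4
  exact_counts: false
domain_marginals:
  attention_vigilance: 0.192
  reasoning_problem_solving: 0.704
  speed_of_processing: 0.151
  verbal_learning_memory: 0.166
  working_memory: 0.271
confounder_rates:
  negation: 0.10
  question: 0.04
  goal: 0.04
  family_history: 0.04
notes_per_patient: {mu: 4, size: 1.0, min: 1}
markup_probability: 0.5
demographics:
  age: {mean: 47.5, sd: 14.3, min: 18, max: 90}
  under_18_rate: 0.05
  gender: {Male: 0.625, Female: 0.375}
  race: {White: 0.42, Black: 0.26, Asian: 0.055, Other: 0.175, Unknown: 0.09}
  ethnicity: {Hispanic: 0.06, Non-Hispanic: 0.56, Unknown: 0.38}
  region: {Northeast: 0.13, Midwest: 0.16, South: 0.25, West: 0.44, Other: 0.02}
  payer: {Medicaid: 0.705, Medicare: 0.075, Dual Medicare-Medicaid: 0.085,
          Commercial: 0.048, Self-Insured: 0.005, Other: 0.01, Unknown: 0.072}
comorbidity_prevalences:
  anxiety: {impaired: 0.390, unimpaired: 0.288}
  bipolar_disorder: {impaired: 0.239, unimpaired: 0.213}
  depression: {impaired: 0.363, unimpaired: 0.310}
  panic_disorder: {impaired: 0.043, unimpaired: 0.026}
  ptsd: {impaired: 0.108, unimpaired: 0.082}
  substance_use_disorder: {impaired: 0.334, unimpaired: 0.308}
cci:
  impaired: {mean: 0.80, sd: 1.50}
  unimpaired: {mean: 0.80, sd: 1.43}
bmi:
  impaired: {mean: 29.7, sd: 6.5}
  unimpaired: {mean: 30.1, sd: 6.3}
utilization:
  outpatient: {impaired: {mu: 45.0, size: 4.0}, unimpaired: {mu: 40.3, size: 4.0}}
  pharmacy: {impaired: {mu: 37.8, size: 4.0}, unimpaired: {mu: 35.9, size: 4.0}}
  er: {impaired: {mu: 1.43, size: 1.0}, unimpaired: {mu: 1.38, size: 1.0}}
  inpatient: {impaired: {mu: 0.36, size: 1.0}, unimpaired: {mu: 0.32, size: 1.0}}
  los_per_admission: {impaired: {mean: 17.4}, unimpaired: {mean: 15.4}, size: 5.0}
  therapy_days: {impaired: {mu: 10.6, size: 3.0}, unimpaired: {mu: 8.7, size: 3.0}}
  er_psychiatric_fraction: {impaired: 0.175, unimpaired: 0.167}
  inpatient_primary_sz_fraction: {impaired: 0.50, unimpaired: 0.50}
treatment_rates:
  psychotherapy: {impaired: 0.329, unimpaired: 0.240}
  cbt: {impaired: 0.002, unimpaired: 0.001}
  family_therapy: {impaired: 0.009, unimpaired: 0.007}
  psychosocial_rehab: {impaired: 0.045, unimpaired: 0.040}
  group_therapy: {impaired: 0.037, unimpaired: 0.029}
  fga: {impaired: 0.198, unimpaired: 0.193}
  sga: {impaired: 0.801, unimpaired: 0.709}
  mood_stabilizer: {impaired: 0.226, unimpaired: 0.184}
  antidepressant: {impaired: 0.574, unimpaired: 0.508}
eligibility:
  encounters_rate: 0.85
  activity_rate: 0.85
  exclusion_dx_rate: 0.10
  benign_exclusion_code_rate: 0.05
  enrollment_rate: 0.60
dx_codes:
  schizophrenia: ["F20.0", "F20.9", "295.90"]
  psychiatric: ["F31.9", "F41.1", "F32.9"]
  somatic: ["I10", "E11.9", "J06.9"]
  comorbidity:
    anxiety: ["F41.1", "F41.9"]
    panic_disorder: ["F41.0"]
    bipolar_disorder: ["F31.9"]
    depression: ["F32.9", "F33.1"]
    ptsd: ["F43.10"]
    substance_use_disorder: ["F10.20"]
  exclusion:
    dementia: ["F03.90"]
    frontotemporal_disease: ["G31.09"]
    prion_disease: ["A81.9"]
    multiple_sclerosis: ["G35"]
    parkinsons_disease: ["G20"]
    stroke: ["I63.9"]
    traumatic_brain_injury: ["S06.9X9"]
    autism_spectrum_disorder: ["F84.0"]
    epilepsy: ["G40.909"]
    intellectual_disability: ["F71"]
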