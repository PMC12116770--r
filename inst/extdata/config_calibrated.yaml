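# Calibrated generator configuration.
#
# Group-level parameters (documentation prevalence, domain marginals,
# comorbidity rates, CCI/BMI moments, utilization means) reproduce the
# published study-population summaries for the EHR and linked-claims cohorts;
# dispersion sizes, confounder rates, the notes-per-patient law and the code
# pools are generator modelling choices documented in the package vignette.
#
# domain_marginals are conditional on documented impairment (the denominator
# used in the corpus report); the generator calibrates raw embedding
# probabilities so these conditional marginals are recovered exactly in
# expectation.  Negative binomial streams use the (mu, size) parameterization
# with variance mu + mu^2/size.
n_patients: 1000
date_window:
  start: "2016-01-01"
  end: "2022-02-28"
documentation:
  mode: note_coupled          # documentation probability rises with note count
  prevalence: 0.252           # used by mode: fixed
  exact_counts: false
  coupling:                   # logistic in log(note count), fit through anchors
    anchors:
      - {notes: 3, prob: 0.025}
      - {notes: 70, prob: 0.523}
domain_marginals:
  attention_vigilance: 0.192
  reasoning_problem_solving: 0.704
  speed_of_processing: 0.151
  verbal_learning_memory: 0.166
  working_memory: 0.271
category_weights:             # relative within-domain planting weights
  attention_vigilance:
    reduced attention: 16.2
    poor concentration: 4.2
    difficulty understanding: 0.7
    difficulty staying focused: 0.6
  reasoning_problem_solving:
    insight and judgment: 69.8
    difficulty learning: 0.9
    manage bills money: 0.7
    learning new technology: 0.5
    handling changes: 0.4
    planning: 0.2
    difficulties with concrete thinking: 0.2
    difficulty problem solving: 0.03
  speed_of_processing:
    poverty of thought: 7.7
    thought blocking: 5.4
    participate in conversation: 1.4
    slow thinking: 1.2
    difficulty integrating thoughts, feelings, and behavior: 1.2
    ability to perform tasks: 0.2
    unable to do things quickly: 0.1
  verbal_learning_memory:
    difficulty expressing themselves: 10.8
    hindered speech: 7.4
    limited vocabulary: 0.9
    follow conversation: 0.3
    remembering what they are going to say: 0.1
  working_memory:
    poor memory: 14.1
    remembering how to get to places: 7.2
    difficulties remembering things: 6.3
    remembering names of people: 2.6
    remembering where they put things: 0.1
    remembering chores and responsibilities: 0.04
confounder_rates:             # decoy sentences per note, both groups
  negation: 0.10
  question: 0.04
  goal: 0.04
  family_history: 0.04
notes_per_patient: {mu: 12, size: 0.6, min: 1}
markup_probability: 0.5
demographics:
  age: {mean: 47.5, sd: 14.3, min: 18, max: 90}
  under_18_rate: 0.02
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
  encounters_rate: 0.95       # P(>= 2 outpatient schizophrenia encounters)
  activity_rate: 0.95         # P(>= 12 months pre-index EHR activity)
  exclusion_dx_rate: 0.04     # P(carries an exclusionary diagnosis)
  benign_exclusion_code_rate: 0.02  # prior-to-index-type code dated post-index
  enrollment_rate: 0.60       # P(>= 12 months continuous post-index coverage)
dx_codes:
  schizophrenia: ["F20.0", "F20.1", "F20.2", "F20.3", "F20.5", "F20.9",
                  "295.10", "295.30", "295.60", "295.90"]
  psychiatric: ["F31.9", "F41.1", "F32.9", "F43.10", "F10.20", "F41.0", "F25.0"]
  somatic: ["I10", "E11.9", "J06.9", "M54.5", "K21.9", "E78.5"]
  comorbidity:
    anxiety: ["F41.1", "F41.9"]
    panic_disorder: ["F41.0"]
    bipolar_disorder: ["F31.9"]
    depression: ["F32.9", "F33.1"]
    ptsd: ["F43.10"]
    substance_use_disorder: ["F10.20", "F11.20", "F12.20"]
  exclusion:
    dementia: ["F03.90", "G30.9"]
    frontotemporal_disease: ["G31.09"]
    prion_disease: ["A81.9"]
    multiple_sclerosis: ["G35"]
    parkinsons_disease: ["G20"]
    stroke: ["I63.9"]
    traumatic_brain_injury: ["S06.9X9"]
    autism_spectrum_disorder: ["F84.0"]
    epilepsy: ["G40.909"]
    intellectual_disability: ["F71", "F79"]
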