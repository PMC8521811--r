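# Default pediatric cut-points for the seven Life's Simple 7 factors,
# AHA-style child/adolescent conventions. Every factor has exactly three
# categories: ideal / intermediate / poor. Boundary convention is half-open
# on the worse direction: a value equal to a boundary falls in the
# worse-adjacent category (e.g. cholesterol 170 is intermediate, 200 poor).
# All values are overridable by supplying a config with the same schema.
bmi_percentile:
  type: range
  direction: lower_better     # units: percentile 0-100
  ideal_max: 85               # ideal  < 85
  intermediate_max: 95        # 85 <= v < 95 intermediate; >= 95 poor
blood_pressure:
  type: blood_pressure        # units: mmHg, value is [systolic, diastolic]
  systolic:
    ideal_max: 120
    intermediate_max: 140
  diastolic:
    ideal_max: 80
    intermediate_max: 90
cholesterol:
  type: range
  direction: lower_better     # units: mg/dL total cholesterol
  ideal_max: 170
  intermediate_max: 200
glucose:
  type: range
  direction: lower_better     # units: mg/dL fasting glucose
  ideal_max: 100
  intermediate_max: 126
smoking:
  type: categorical           # never / former / current
  map:
    never: ideal
    former: intermediate
    current: poor
physical_activity:
  type: range
  direction: higher_better    # units: min/week MVPA
  ideal_min: 420              # 60 min/day x 7
  poor_max: 0                 # any activity at all beats "inactive"
diet:
  type: range
  direction: higher_better    # units: count of healthy components, 0-5
  ideal_min: 4
  poor_max: 1
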