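# Synthetic default fitness-classification table (NOT the copyrighted ACSM
# norm table; editable). Categories are ordered lowest -> highest fitness.
# `cutpoints` are the upper bounds (mL/kg/min, estimated VO2max) separating
# the five categories within each sex x age stratum: a value below the first
# cutpoint falls in the first (lowest) category, and so on; values at or
# above the last cutpoint fall in the highest.
source_table: synthetic-default-v1
categories: [very_poor, poor, fair, good, excellent]
bands:
  female:
    - {age_min: 20, age_max: 29, cutpoints: [31, 35, 39, 43]}
    - {age_min: 30, age_max: 39, cutpoints: [29, 33, 37, 41]}
    - {age_min: 40, age_max: 49, cutpoints: [28, 31, 35, 39]}
    - {age_min: 50, age_max: 59, cutpoints: [26, 29, 33, 37]}
  male:
    - {age_min: 20, age_max: 29, cutpoints: [36, 41, 45, 50]}
    - {age_min: 30, age_max: 39, cutpoints: [34, 38, 43, 48]}
    - {age_min: 40, age_max: 49, cutpoints: [31, 35, 40, 45]}
    - {age_min: 50, age_max: 59, cutpoints: [28, 32, 36, 41]}
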