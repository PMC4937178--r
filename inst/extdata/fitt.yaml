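# Default FITT prescription table: per fitness category, the admissible
# ranges of intensity (fraction of heart-rate reserve), session duration
# (minutes) and weekly frequency (sessions/week). The prescription engine
# selects the MINIMUM of each range. The lowest band's minima (0.30 HRR,
# 30 min, 3x/week) mirror the sedentary worked example; the remaining bands
# are editable defaults following the usual progressive-overload shape.
very_poor: {intensity: [0.30, 0.45], duration_min: [30, 45], frequency: [3, 5]}
poor:      {intensity: [0.40, 0.55], duration_min: [30, 50], frequency: [3, 5]}
fair:      {intensity: [0.55, 0.70], duration_min: [35, 55], frequency: [3, 5]}
good:      {intensity: [0.65, 0.80], duration_min: [40, 60], frequency: [4, 6]}
excellent: {intensity: [0.70, 0.85], duration_min: [45, 60], frequency: [4, 6]}
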