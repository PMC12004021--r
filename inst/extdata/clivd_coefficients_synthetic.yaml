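# Synthetic stand-in coefficient set for the CLivD 10-year chronic liver
# disease risk score.
#
# PROVENANCE / IMPORTANT: these are NOT the published CLivD coefficients.
# The functional form (10-year risk = 1 - baseline_survival ^ exp(linear
# predictor)), the input set (sex, age, current smoking, weekly alcohol
# servings, waist-hip ratio, diabetes; the lab variant adds log GGT), the
# variant switch and the coefficient signs follow the published model; the
# numeric values below are package-chosen, calibrated once to plausible
# Finnish general-population 10-year severe liver disease incidence
# (reference profile: female, age 55, non-smoker, 0 servings/week,
# WHR 1.0, no diabetes -> 1.0% ten-year risk). Users with access to the
# published supplementary material can substitute their own transcription
# file; the loader validates names and finiteness, never hard-codes values.
provenance: >
  Synthetic stand-in transcription; structure and signs follow the published
  CLivD model, numeric values are package-chosen (see package vignette).
functional_form: "ten_year_risk = 1 - baseline_survival ^ exp(lp)"
cutoffs:
  low: 0.05
  high: 0.10
age_window:
  min: 40
  max: 70
variants:
  nonlab:
    baseline_survival: 0.990
    centering:
      age: 55
      whr: 1.0
    coefficients:
      male: 0.35
      age_per_year: 0.060
      smoker: 0.60
      alcohol_per_serving_week: 0.022
      whr_per_unit: 6.0
      diabetes: 0.40
  lab:
    baseline_survival: 0.992
    centering:
      age: 55
      whr: 1.0
      log_ggt: 3.401197
    coefficients:
      male: 0.32
      age_per_year: 0.055
      smoker: 0.55
      alcohol_per_serving_week: 0.019
      whr_per_unit: 6.0
      diabetes: 0.33
      log_ggt: 0.45
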