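# Default six-domain rule base. Thresholds are implementation-chosen,
# anchored to widely used clinical cut-points (BP control <130/80 mmHg,
# prediabetes glucose >=100 mg/dL, cholesterol >=200 mg/dL, triglycerides
# >=150 mg/dL, overweight BMI >=25, underweight BMI <18.5, adult sleep
# window 7-9 h). Edit values here, never in code.
fallbacks:
  physical_activity: maintain
  stress: maintain
  nutrition: maintain
  sleep: general
  adherence: general
  general_behaviors: reduce
rules:
  # -- physical activity: weekly exercise frequency bands -----------------
  - id: pa_initiate
    domain: physical_activity
    when:
      - [activity_days, lt, 0.5]
    then: initiate
    weight: 1
    note: sedentary patients start a program
  - id: pa_increase
    domain: physical_activity
    when:
      - [activity_days, ge, 0.5]
      - [activity_days, lt, 3]
    then: increase
    weight: 1
  - id: pa_maintain
    domain: physical_activity
    when:
      - [activity_days, ge, 3]
    then: maintain
    weight: 1
  # -- stress management: stress exposure x BP control --------------------
  - id: st_urgent_sbp
    domain: stress
    when:
      - [stress_level, eq, high]
      - [sbp, ge, 130]
    then: urgent
    weight: 1
  - id: st_urgent_dbp
    domain: stress
    when:
      - [stress_level, eq, high]
      - [dbp, ge, 80]
    then: urgent
    weight: 1
  - id: st_reduce
    domain: stress
    when:
      - [stress_level, eq, high]
    then: reduce
    weight: 1
  # -- nutrition: metabolic indicators + BMI ------------------------------
  - id: nu_glucose
    domain: nutrition
    when:
      - [glucose, ge, 100]
    then: reduce
    weight: 1
  - id: nu_cholesterol
    domain: nutrition
    when:
      - [cholesterol, ge, 200]
    then: reduce
    weight: 1
  - id: nu_triglycerides
    domain: nutrition
    when:
      - [triglycerides, ge, 150]
    then: reduce
    weight: 1
  - id: nu_bmi_high
    domain: nutrition
    when:
      - [bmi, ge, 25]
    then: reduce
    weight: 1
  - id: nu_underweight
    domain: nutrition
    when:
      - [bmi, lt, 18.5]
    then: increase
    weight: 1
  # -- sleep: nightly rest duration x BP pattern --------------------------
  - id: sl_short_sbp
    domain: sleep
    when:
      - [sleep_hours, lt, 7]
      - [sbp, ge, 130]
    then: urgent
    weight: 1
  - id: sl_short_dbp
    domain: sleep
    when:
      - [sleep_hours, lt, 7]
      - [dbp, ge, 80]
    then: urgent
    weight: 1
  - id: sl_long_sbp
    domain: sleep
    when:
      - [sleep_hours, gt, 9]
      - [sbp, ge, 130]
    then: urgent
    weight: 1
  - id: sl_long_dbp
    domain: sleep
    when:
      - [sleep_hours, gt, 9]
      - [dbp, ge, 80]
    then: urgent
    weight: 1
  # -- therapeutic adherence: compliance x BP control ---------------------
  - id: ad_urgent_sbp
    domain: adherence
    when:
      - [antihypertensive_medication, eq, "yes"]
      - [sbp, ge, 130]
    then: urgent
    weight: 1
  - id: ad_urgent_dbp
    domain: adherence
    when:
      - [antihypertensive_medication, eq, "yes"]
      - [dbp, ge, 80]
    then: urgent
    weight: 1
  - id: ad_maintain
    domain: adherence
    when:
      - [medication_adherence, eq, adherent]
      - [sbp, lt, 130]
      - [dbp, lt, 80]
    then: maintain
    weight: 1
  # -- general behaviors: substance use and screen time -------------------
  - id: gb_smoker
    domain: general_behaviors
    when:
      - [smoking_status, eq, current]
    then: urgent
    weight: 1
  - id: gb_alcohol_frequent
    domain: general_behaviors
    when:
      - [alcohol_consumption, eq, frequent]
    then: urgent
    weight: 1
  - id: gb_screen
    domain: general_behaviors
    when:
      - [screen_hours, ge, 6]
    then: reduce
    weight: 1
  - id: gb_alcohol_occasional
    domain: general_behaviors
    when:
      - [alcohol_consumption, eq, occasional]
    then: reduce
    weight: 1
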