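{
  "sex": "gender",
  "age_years": "age",
  "residence_type": "residence",
  "edu_years": "education_years",
  "living_arrangement": "co_residence",
  "econ_status": "economic_status",
  "sleep_hrs": "sleep_hours",
  "fruit": "fruit_freq",
  "vegetable": "veg_freq",
  "taste_preference": "flavor",
  "smoke_now": "smoking_now",
  "drink_now": "drinking_now",
  "exercise_regular": "regular_exercise",
  "life_rating": "qol_rating",
  "health_self_rating": "health_rating"
}
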