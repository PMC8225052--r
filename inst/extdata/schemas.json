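{
  "dietary_records": {
    "file": "dietary_records.csv",
    "columns": {
      "participant_id": {"type": "character", "required": true},
      "wave": {"type": "integer", "required": true, "allowed": [2009, 2011]},
      "day": {"type": "integer", "required": true, "allowed": [1, 2, 3]},
      "food_id": {"type": "character", "required": true},
      "amount": {"type": "double", "required": true, "min": 0}
    }
  },
  "food_table": {
    "file": "food_table.csv",
    "columns": {
      "food_id": {"type": "character", "required": true},
      "energy_density": {"type": "double", "required": true, "min": 0},
      "food_group": {
        "type": "character", "required": true,
        "allowed": ["staple", "vegetables", "fruits", "eggs", "aquatic",
                    "meat_poultry", "soy_nuts", "dairy", "salt", "oil"]
      }
    }
  },
  "surveys": {
    "file": "surveys.csv",
    "columns": {
      "participant_id": {"type": "character", "required": true},
      "age": {"type": "double", "required": false, "min": 0, "max": 120},
      "gender": {"type": "character", "required": false, "allowed": ["man", "woman"]},
      "weight": {"type": "double", "required": false, "min": 20, "max": 250},
      "height": {"type": "double", "required": false, "min": 0.8, "max": 2.5},
      "region": {"type": "character", "required": false, "allowed": ["south", "north"]},
      "residency": {"type": "character", "required": false, "allowed": ["rural", "urban"]},
      "education": {"type": "character", "required": false,
                    "allowed": ["primary_or_below", "middle_or_above"]},
      "income": {"type": "double", "required": false, "min": 0},
      "income_wave": {"type": "integer", "required": true, "allowed": [2009, 2011]},
      "site_id": {"type": "character", "required": true},
      "marriage": {"type": "character", "required": false, "allowed": ["married", "other"]},
      "smoking": {"type": "character", "required": false, "allowed": ["current", "not"]},
      "alcohol": {"type": "character", "required": false,
                  "allowed": ["ge1_per_week", "lt1_per_week"]},
      "limitation_lift": {"type": "character", "required": false,
                          "allowed": ["no_difficulty", "difficulty", "dont_know"]},
      "limitation_squat": {"type": "character", "required": false,
                           "allowed": ["no_difficulty", "difficulty", "dont_know"]},
      "limitation_stand": {"type": "character", "required": false,
                           "allowed": ["no_difficulty", "difficulty", "dont_know"]},
      "limitation_sit": {"type": "character", "required": false,
                         "allowed": ["no_difficulty", "difficulty", "dont_know"]},
      "limitation_walk": {"type": "character", "required": false,
                          "allowed": ["no_difficulty", "difficulty", "dont_know"]},
      "diabetes": {"type": "character", "required": false, "allowed": ["yes", "no", "dont_know"]},
      "myocardial_infarction": {"type": "character", "required": false,
                                "allowed": ["yes", "no", "dont_know"]},
      "stroke": {"type": "character", "required": false, "allowed": ["yes", "no", "dont_know"]},
      "apoplexy": {"type": "character", "required": false, "allowed": ["yes", "no", "dont_know"]},
      "asthma": {"type": "character", "required": false, "allowed": ["yes", "no", "dont_know"]},
      "hypertension_diagnosed": {"type": "character", "required": false,
                                 "allowed": ["yes", "no", "dont_know"]},
      "sbp": {"type": "double", "required": false, "min": 60, "max": 300},
      "dbp": {"type": "double", "required": false, "min": 30, "max": 200},
      "cog_immediate": {"type": "integer", "required": false, "min": 0, "max": 10},
      "cog_delayed": {"type": "integer", "required": false, "min": 0, "max": 10},
      "cog_serial7s": {"type": "integer", "required": false, "min": 0, "max": 5},
      "cog_backward": {"type": "character", "required": false,
                       "allowed": ["first_try", "second_try", "fail"]},
      "pss_01": {"type": "character", "required": false,
                 "allowed": ["never", "almost_never", "sometimes", "fairly_often", "very_often", "dont_know"]},
      "pss_02": {"type": "character", "required": false,
                 "allowed": ["never", "almost_never", "sometimes", "fairly_often", "very_often", "dont_know"]},
      "pss_03": {"type": "character", "required": false,
                 "allowed": ["never", "almost_never", "sometimes", "fairly_often", "very_often", "dont_know"]},
      "pss_04": {"type": "character", "required": false,
                 "allowed": ["never", "almost_never", "sometimes", "fairly_often", "very_often", "dont_know"]},
      "pss_05": {"type": "character", "required": false,
                 "allowed": ["never", "almost_never", "sometimes", "fairly_often", "very_often", "dont_know"]},
      "pss_06": {"type": "character", "required": false,
                 "allowed": ["never", "almost_never", "sometimes", "fairly_often", "very_often", "dont_know"]},
      "pss_07": {"type": "character", "required": false,
                 "allowed": ["never", "almost_never", "sometimes", "fairly_often", "very_often", "dont_know"]},
      "pss_08": {"type": "character", "required": false,
                 "allowed": ["never", "almost_never", "sometimes", "fairly_often", "very_often", "dont_know"]},
      "pss_09": {"type": "character", "required": false,
                 "allowed": ["never", "almost_never", "sometimes", "fairly_often", "very_often", "dont_know"]},
      "pss_10": {"type": "character", "required": false,
                 "allowed": ["never", "almost_never", "sometimes", "fairly_often", "very_often", "dont_know"]},
      "pss_11": {"type": "character", "required": false,
                 "allowed": ["never", "almost_never", "sometimes", "fairly_often", "very_often", "dont_know"]},
      "pss_12": {"type": "character", "required": false,
                 "allowed": ["never", "almost_never", "sometimes", "fairly_often", "very_often", "dont_know"]},
      "pss_13": {"type": "character", "required": false,
                 "allowed": ["never", "almost_never", "sometimes", "fairly_often", "very_often", "dont_know"]},
      "pss_14": {"type": "character", "required": false,
                 "allowed": ["never", "almost_never", "sometimes", "fairly_often", "very_often", "dont_know"]},
      "life_quality": {"type": "character", "required": false,
                       "allowed": ["very_good", "good", "fair", "bad", "very_bad", "dont_know"]}
    }
  },
  "sites": {
    "file": "sites.csv",
    "columns": {
      "site_id": {"type": "character", "required": true},
      "region": {"type": "character", "required": true, "allowed": ["south", "north"]}
    }
  }
}
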