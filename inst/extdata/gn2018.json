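{
  "sites": [
    {
      "name": "guatemala",
      "n_clusters": 23,
      "births_per_cluster_year": 403,
      "years": [2010, 2011, 2012, 2013, 2014, 2015, 2016, 2017, 2018],
      "stillbirth_rate": 0.02,
      "yearly_trend": 0.995,
      "cluster_sd": 0.15,
      "maceration": {
        "macerated": 0.204,
        "non_macerated": 0.743,
        "unknown": 0.053
      },
      "cluster_start_years": {}
    },
    {
      "name": "drc",
      "n_clusters": 10,
      "births_per_cluster_year": 357,
      "years": [2010, 2011, 2012, 2013, 2014, 2015, 2016, 2017, 2018],
      "stillbirth_rate": 0.04,
      "yearly_trend": 0.995,
      "cluster_sd": 0.15,
      "maceration": {
        "macerated": 0.351,
        "non_macerated": 0.635,
        "unknown": 0.014
      },
      "cluster_start_years": {}
    },
    {
      "name": "zambia",
      "n_clusters": 18,
      "births_per_cluster_year": 390,
      "years": [2010, 2011, 2012, 2013, 2014, 2015, 2016, 2017, 2018],
      "stillbirth_rate": 0.0197,
      "yearly_trend": 0.995,
      "cluster_sd": 0.15,
      "maceration": {
        "macerated": 0.36,
        "non_macerated": 0.624,
        "unknown": 0.016
      },
      "cluster_start_years": {}
    },
    {
      "name": "kenya",
      "n_clusters": 21,
      "births_per_cluster_year": 396,
      "years": [2010, 2011, 2012, 2013, 2014, 2015, 2016, 2017, 2018],
      "stillbirth_rate": 0.0219,
      "yearly_trend": 0.995,
      "cluster_sd": 0.15,
      "maceration": {
        "macerated": 0.219,
        "non_macerated": 0.732,
        "unknown": 0.049
      },
      "cluster_start_years": {}
    },
    {
      "name": "belagavi",
      "n_clusters": 24,
      "births_per_cluster_year": 572,
      "years": [2010, 2011, 2012, 2013, 2014, 2015, 2016, 2017, 2018],
      "stillbirth_rate": 0.0251,
      "yearly_trend": 0.995,
      "cluster_sd": 0.15,
      "maceration": {
        "macerated": 0.36,
        "non_macerated": 0.635,
        "unknown": 0.005
      },
      "cluster_start_years": {}
    },
    {
      "name": "nagpur",
      "n_clusters": 23,
      "births_per_cluster_year": 401,
      "years": [2010, 2011, 2012, 2013, 2014, 2015, 2016, 2017, 2018],
      "stillbirth_rate": 0.0325,
      "yearly_trend": 0.9215,
      "cluster_sd": 0.15,
      "maceration": {
        "macerated": 0.192,
        "non_macerated": 0.689,
        "unknown": 0.119
      },
      "cluster_start_years": {}
    },
    {
      "name": "pakistan",
      "n_clusters": 24,
      "births_per_cluster_year": 426,
      "years": [2010, 2011, 2012, 2013, 2014, 2015, 2016, 2017, 2018],
      "stillbirth_rate": 0.056,
      "yearly_trend": 0.9714,
      "cluster_sd": 0.15,
      "maceration": {
        "macerated": 0.309,
        "non_macerated": 0.544,
        "unknown": 0.147
      },
      "cluster_start_years": {}
    }
  ],
  "covariates": [
    {
      "name": "age_group",
      "levels": ["20_35", "lt20", "gt35"],
      "prevalence": [0.827, 0.128, 0.045],
      "rr": [1, 1, 1]
    },
    {
      "name": "education",
      "levels": ["university_plus", "none", "primary", "secondary"],
      "prevalence": [0.069, 0.237, 0.295, 0.399],
      "rr": [1, 1, 1, 1]
    },
    {
      "name": "parity_group",
      "levels": ["1_2", "0", "gt2"],
      "prevalence": [0.422, 0.323, 0.255],
      "rr": [1, 1, 1]
    },
    {
      "name": "anc_group",
      "levels": ["ge3", "0", "1_2"],
      "prevalence": [0.81, 0.022, 0.168],
      "rr": [1, 3.5, 2.2]
    },
    {
      "name": "attendant",
      "levels": ["physician", "nurse_midwife_hw", "tba", "family_other"],
      "prevalence": [0.358, 0.373, 0.219, 0.05],
      "rr": [1, 0.6, 0.5, 2.1]
    },
    {
      "name": "location",
      "levels": ["hospital", "clinic", "home_other"],
      "prevalence": [0.436, 0.312, 0.252],
      "rr": [1, 1, 1]
    },
    {
      "name": "mode",
      "levels": ["vaginal", "vaginal_assisted", "cesarean"],
      "prevalence": [0.852, 0.009, 0.139],
      "rr": [1, 1, 1]
    },
    {
      "name": "sex",
      "levels": ["female", "male", "unknown"],
      "prevalence": [0.484, 0.514, 0.002],
      "rr": [1, 1.2, 1]
    },
    {
      "name": "multiple",
      "levels": ["false", "true"],
      "prevalence": [0.982, 0.018],
      "rr": [1, 1]
    },
    {
      "name": "presentation",
      "levels": ["cephalic", "breech_transverse", "unknown"],
      "prevalence": [0.975, 0.02, 0.005],
      "rr": [1, 1, 1]
    }
  ],
  "conditions": {
    "trauma": {
      "p_stillbirth": 0.0002,
      "p_live": 0.0001
    },
    "major_anomaly": {
      "p_stillbirth": 0.074,
      "p_live": 0.005
    },
    "maternal_infection": {
      "p_stillbirth": 0.105,
      "p_live": 0.02
    },
    "fetal_infection": {
      "p_stillbirth": 0.17,
      "p_live": 0.01
    },
    "hypertensive_disease": {
      "p_stillbirth": 0.097,
      "p_live": 0.03
    },
    "antepartum_hemorrhage": {
      "p_stillbirth": 0.113,
      "p_live": 0.01
    },
    "obstructed_prolonged_labor": {
      "p_stillbirth": 0.206,
      "p_live": 0.04
    },
    "breech_transverse": {
      "p_stillbirth": 0.097,
      "p_live": 0.02
    },
    "other_asphyxia_condition": {
      "p_stillbirth": 0.35,
      "p_live": 0.03
    }
  },
  "prior_loss": {
    "prob_no_given_parous": 0.053,
    "rr_no": 1
  },
  "exclusions": {
    "miscarriage": 0.028,
    "termination": 0.002,
    "missing": 0.006
  },
  "ga_missing_prob": 0.03,
  "bw_missing_prob": 0.02,
  "flag_unknown_prob": 0.01,
  "ga_dist": {
    "live": {
      "mean": 38.8,
      "sd": 1.9,
      "min": 24,
      "max": 43
    },
    "stillbirth": {
      "mean": 35.5,
      "sd": 4.5,
      "min": 20,
      "max": 43
    }
  },
  "bw_model": {
    "at_40wk": 3250,
    "per_week": 170,
    "stillbirth_shift": -150,
    "sd": 350,
    "min": 400,
    "max": 5500
  },
  "seed": 20180101
}
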