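{
  "asc": 1.52,
  "betas": {
    "place:gp_surgery": -0.3,
    "place:outpatient_clinic": 0.16,
    "place:home_visit": 0.15,
    "review:comprehensive": 0.15,
    "support:therapists_and_social_worker": 0.19,
    "support:none": -0.23,
    "support:social_worker_only": -0.15,
    "waiting:2_weeks": 0.25,
    "waiting:4_weeks": 0.1
  },
  "se": null,
  "ci95": null,
  "vcov": null,
  "log_likelihood": "NA",
  "n_tasks": "NA",
  "converged": null,
  "design": [
    {
      "name": "place",
      "levels": [
        "gp_surgery",
        "home_visit",
        "outpatient_clinic"
      ],
      "reference": "gp_surgery",
      "coding": "dummy"
    },
    {
      "name": "review",
      "levels": [
        "non_medicinal_only",
        "comprehensive"
      ],
      "reference": "non_medicinal_only",
      "coding": "dummy"
    },
    {
      "name": "support",
      "levels": [
        "none",
        "social_worker_only",
        "therapists_and_social_worker"
      ],
      "reference": "none",
      "coding": "dummy"
    },
    {
      "name": "waiting",
      "levels": [
        "2_weeks",
        "4_weeks",
        "8_weeks"
      ],
      "reference": "8_weeks",
      "coding": "dummy",
      "values": {
        "2_weeks": 2,
        "4_weeks": 4,
        "8_weeks": 8
      }
    }
  ]
}
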