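{
  "format_version": "1.0",
  "source": {"id": "SYNEX:PD-2005", "year": 2005},
  "cohorts": [
    {
      "cohort_label": "cohort-1",
      "path_diagnosis": "PD",
      "n_cases": 120,
      "n_female": 48,
      "n_male": 72,
      "onset": {"mean": 62.4, "sd": 10.8, "n": 120},
      "death": {"mean": 77.1, "sd": 8.1, "n": 120},
      "duration": {"mean": 14.7, "sd": 6.8, "n": 120},
      "onset_reference": "symptom_onset",
      "clinical_diagnoses": [
        {"label": "PD", "count": 104},
        {"label": "MSA", "count": 7},
        {"label": "OTHER:AD", "count": 9}
      ],
      "phenotypes": [
        {"term_id": "HP:0002322", "n_present": 90, "n_assessed": 120},
        {"term_id": "HP:0002067", "n_present": 114, "n_assessed": 120},
        {"term_id": "HP:0001278", "n_present": 36, "n_assessed": 120},
        {"term_id": "HP:0033712", "n_present": 48, "n_assessed": 120},
        {"term_id": "HP:0001251", "n_present": 6, "n_assessed": 120},
        {"term_id": "HP:0100543", "n_present": 36, "n_assessed": 120}
      ],
      "dual_diagnosis": false
    },
    {
      "cohort_label": "cohort-2",
      "path_diagnosis": "PD",
      "n_cases": 40,
      "onset": {"mean": 63.9, "sd": 11.5, "n": 40},
      "duration": {"mean": 13.9, "sd": 7.2, "n": 40},
      "onset_reference": "diagnosis",
      "phenotypes": [
        {"term_id": "HP:0002322", "n_present": 31, "n_assessed": 40},
        {"term_id": "HP:0001278", "n_present": 13, "n_assessed": 40},
        {"term_id": "HP:0033712", "n_present": 15, "n_assessed": 40}
      ],
      "dual_diagnosis": false
    }
  ]
}
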