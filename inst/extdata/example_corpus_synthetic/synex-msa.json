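{
  "format_version": "1.0",
  "source": {"id": "SYNEX:MSA-2011", "year": 2011},
  "cohorts": [
    {
      "cohort_label": "cohort-1",
      "path_diagnosis": "MSA",
      "n_cases": 80,
      "n_female": 34,
      "n_male": 46,
      "onset": {"mean": 59.0, "sd": 9.3, "n": 80},
      "death": {"mean": 66.5, "sd": 8.6, "n": 80},
      "duration": {"mean": 7.2, "sd": 2.7, "n": 80},
      "onset_reference": "symptom_onset",
      "clinical_diagnoses": [
        {"label": "MSA", "count": 66},
        {"label": "PD", "count": 7},
        {"label": "PSP", "count": 5},
        {"label": "OTHER:AD", "count": 2}
      ],
      "phenotypes": [
        {"term_id": "HP:0002322", "n_present": 24, "n_assessed": 80},
        {"term_id": "HP:0002067", "n_present": 68, "n_assessed": 80},
        {"term_id": "HP:0001278", "n_present": 60, "n_assessed": 80},
        {"term_id": "HP:0033712", "n_present": 40, "n_assessed": 80},
        {"term_id": "HP:0001251", "n_present": 44, "n_assessed": 80},
        {"term_id": "HP:0010307", "n_present": 24, "n_assessed": 80},
        {"term_id": "HP:0100543", "n_present": 16, "n_assessed": 80}
      ],
      "dual_diagnosis": false
    }
  ]
}
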