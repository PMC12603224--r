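{
  "format_version": "1.0",
  "source": {"id": "SYNEX:PSP-DLB-2016", "year": 2016},
  "cohorts": [
    {
      "cohort_label": "psp",
      "path_diagnosis": "PSP",
      "n_cases": 60,
      "onset": {"mean": 65.8, "sd": 8.0, "n": 60},
      "death": {"mean": 73.5, "sd": 7.9, "n": 60},
      "duration": {"mean": 7.5, "sd": 3.7, "n": 60},
      "onset_reference": "symptom_onset",
      "clinical_diagnoses": [
        {"label": "PSP", "count": 48},
        {"label": "PD", "count": 5},
        {"label": "CBS", "count": 3},
        {"label": "MSA", "count": 3},
        {"label": "OTHER:FTD", "count": 1}
      ],
      "phenotypes": [
        {"term_id": "HP:0002322", "n_present": 7, "n_assessed": 60},
        {"term_id": "HP:0002067", "n_present": 54, "n_assessed": 60},
        {"term_id": "HP:0000605", "n_present": 42, "n_assessed": 60},
        {"term_id": "HP:0002527", "n_present": 48, "n_assessed": 60},
        {"term_id": "HP:0001278", "n_present": 9, "n_assessed": 60},
        {"term_id": "HP:0033712", "n_present": 6, "n_assessed": 60},
        {"term_id": "HP:0100543", "n_present": 27, "n_assessed": 60}
      ],
      "dual_diagnosis": false
    },
    {
      "cohort_label": "dlb",
      "path_diagnosis": "DLB",
      "n_cases": 50,
      "onset": {"mean": 69.4, "sd": 10.2, "n": 50},
      "death": {"mean": 78.6, "sd": 8.4, "n": 50},
      "duration": {"mean": 7.9, "sd": 5.5, "n": 50},
      "onset_reference": "symptom_onset",
      "clinical_diagnoses": [
        {"label": "DLB", "count": 39},
        {"label": "MSA", "count": 4},
        {"label": "PD", "count": 1},
        {"label": "OTHER:AD", "count": 6}
      ],
      "phenotypes": [
        {"term_id": "HP:0002322", "n_present": 22, "n_assessed": 50},
        {"term_id": "HP:0002067", "n_present": 40, "n_assessed": 50},
        {"term_id": "HP:0001278", "n_present": 23, "n_assessed": 50},
        {"term_id": "HP:0033712", "n_present": 28, "n_assessed": 50},
        {"term_id": "HP:0100543", "n_present": 45, "n_assessed": 50},
        {"term_id": "HP:0000738", "n_present": 32, "n_assessed": 50}
      ],
      "dual_diagnosis": false
    }
  ]
}
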