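format-version: 1.2
data-version: metaphen/mini-2026-01
remark: Synthetic ~30-term excerpt in the style of the Human Phenotype Ontology, covering the motor, autonomic, sleep and cognitive branches used by Parkinsonian-disorder annotations. Term ids follow HPO where the term exists there; this file is a test fixture, not an HPO release.

[Term]
id: HP:0000001
name: All

[Term]
id: HP:0000118
name: Phenotypic abnormality
is_a: HP:0000001 ! All

[Term]
id: HP:0012638
name: Abnormal nervous system physiology
is_a: HP:0000118 ! Phenotypic abnormality

[Term]
id: HP:0011442
name: Abnormal central motor function
is_a: HP:0012638 ! Abnormal nervous system physiology

[Term]
id: HP:0001337
name: Tremor
is_a: HP:0011442 ! Abnormal central motor function

[Term]
id: HP:0002322
name: Resting tremor
is_a: HP:0001337 ! Tremor

[Term]
id: HP:0031908
name: Pill-rolling tremor
is_a: HP:0002322 ! Resting tremor

[Term]
id: HP:0002345
name: Action tremor
is_a: HP:0001337 ! Tremor

[Term]
id: HP:0002174
name: Postural tremor
is_a: HP:0001337 ! Tremor

[Term]
id: HP:0002063
name: Rigidity
is_a: HP:0011442 ! Abnormal central motor function

[Term]
id: HP:0002067
name: Bradykinesia
is_a: HP:0011442 ! Abnormal central motor function

[Term]
id: HP:0001251
name: Ataxia
is_a: HP:0011442 ! Abnormal central motor function

[Term]
id: HP:0002527
name: Falls
is_a: HP:0011442 ! Abnormal central motor function

[Term]
id: HP:0000605
name: Supranuclear gaze palsy
is_a: HP:0011442 ! Abnormal central motor function

[Term]
id: HP:0002015
name: Dysphagia
is_a: HP:0011442 ! Abnormal central motor function

[Term]
id: HP:0010307
name: Stridor
is_a: HP:0012638 ! Abnormal nervous system physiology

[Term]
id: HP:0030653
name: Alien limb phenomenon
is_a: HP:0011442 ! Abnormal central motor function

[Term]
id: HP:0012332
name: Abnormal autonomic nervous system physiology
is_a: HP:0012638 ! Abnormal nervous system physiology

[Term]
id: HP:0001278
name: Orthostatic hypotension
is_a: HP:0012332 ! Abnormal autonomic nervous system physiology

[Term]
id: HP:0000020
name: Urinary incontinence
is_a: HP:0012332 ! Abnormal autonomic nervous system physiology

[Term]
id: HP:0100639
name: Erectile dysfunction
is_a: HP:0012332 ! Abnormal autonomic nervous system physiology

[Term]
id: HP:0000458
name: Anosmia
is_a: HP:0012638 ! Abnormal nervous system physiology

[Term]
id: HP:0002360
name: Sleep abnormality
is_a: HP:0012638 ! Abnormal nervous system physiology

[Term]
id: HP:0033712
name: REM sleep behavior disorder
is_a: HP:0002360 ! Sleep abnormality

[Term]
id: HP:0002189
name: Excessive daytime somnolence
is_a: HP:0002360 ! Sleep abnormality

[Term]
id: HP:0011446
name: Abnormality of higher mental function
is_a: HP:0012638 ! Abnormal nervous system physiology

[Term]
id: HP:0100543
name: Cognitive impairment
is_a: HP:0011446 ! Abnormality of higher mental function

[Term]
id: HP:0033676
name: Mild cognitive impairment
is_a: HP:0100543 ! Cognitive impairment

[Term]
id: HP:0000738
name: Hallucinations
is_a: HP:0011446 ! Abnormality of higher mental function

[Term]
id: HP:0041008
name: Cortical sensory loss
is_a: HP:0012638 ! Abnormal nervous system physiology

[Term]
id: HP:0099999
name: Parkinsonian rest tremor (legacy)
is_obsolete: true
replaced_by: HP:0002322
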