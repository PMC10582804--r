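baseline_case,source,variations
Low-risk CES,literature,higher_risk;add_cancer_symptoms;add_inflammatory_symptoms
Low- to midrisk CES,literature,higher_risk;add_cancer_symptoms;add_inflammatory_symptoms
Midrisk CES,literature,higher_risk;add_cancer_symptoms;add_inflammatory_symptoms
High-risk CES,literature,higher_risk;add_cancer_symptoms;add_inflammatory_symptoms
Low-risk fracture,literature,higher_risk;add_cancer_symptoms;add_inflammatory_symptoms
Low- to midrisk fracture,literature,higher_risk;add_cancer_symptoms;add_inflammatory_symptoms
Midrisk fracture,literature,higher_risk;add_cancer_symptoms;add_inflammatory_symptoms
High-risk fracture,literature,higher_risk;add_cancer_symptoms;add_inflammatory_symptoms
Low-risk malignancy,literature,higher_risk;add_inflammatory_symptoms
Low- to midrisk malignancy,literature,higher_risk;add_inflammatory_symptoms
Midrisk malignancy,literature,higher_risk;add_inflammatory_symptoms
High-risk malignancy,literature,higher_risk;add_inflammatory_symptoms
Low-risk infection,literature,higher_risk;add_cancer_symptoms;add_inflammatory_symptoms
Low- to midrisk infection,literature,higher_risk;add_cancer_symptoms;add_inflammatory_symptoms
Midrisk infection,literature,higher_risk;add_cancer_symptoms;add_inflammatory_symptoms
High-risk infection,literature,higher_risk;add_cancer_symptoms;add_inflammatory_symptoms
Inflammatory condition A,real,higher_risk;add_cancer_symptoms
Inflammatory condition B,real,higher_risk;add_cancer_symptoms
Nerve root condition,literature,higher_risk;add_cancer_symptoms;add_inflammatory_symptoms
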