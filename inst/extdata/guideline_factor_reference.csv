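condition,factor_label,node,reported_contained
cauda_equina_syndrome,Unilateral radicular pain,,FALSE
cauda_equina_syndrome,Bilateral radicular pain,bilateral_radicular_pain,TRUE
cauda_equina_syndrome,Dermatomal reduced sensation,,FALSE
cauda_equina_syndrome,Myotomal weakness,myotomal_weakness,TRUE
cauda_equina_syndrome,Changes to bladder function,bladder_function_change,TRUE
cauda_equina_syndrome,Changes to bowel function,bowel_function_change,TRUE
cauda_equina_syndrome,Saddle sensory disturbance,saddle_sensory_disturbance,TRUE
space_occupying_lesion,History of cancer,history_of_cancer,TRUE
space_occupying_lesion,Night pain,night_pain,FALSE
space_occupying_lesion,Requiring strong pain killers,strong_painkillers,TRUE
space_occupying_lesion,Weight loss,weight_loss,TRUE
space_occupying_lesion,Balance issues,,FALSE
space_occupying_lesion,Odd sensations in legs,odd_sensations_in_legs,TRUE
fracture,History of cancer,history_of_cancer,FALSE
fracture,Multiple myeloma,,FALSE
fracture,Osteoporosis,bone_health,TRUE
fracture,Severe pain or worsening pain,,FALSE
fracture,Age,age,TRUE
fracture,Sex,,FALSE
fracture,Smoker,,FALSE
fracture,Pain worse when lying supine,,FALSE
fracture,Early menopause or late menarche,,FALSE
fracture,History of fracture,,FALSE
infective_condition,Immunosuppression,immunosuppression,TRUE
infective_condition,Steroid use,steroid_use,TRUE
infective_condition,Smoking,,FALSE
infective_condition,Obesity,,FALSE
infective_condition,History of TB,history_of_tb,TRUE
infective_condition,Fever,fever,TRUE
infective_condition,Neurological dysfunction,neurological_dysfunction,TRUE
infective_condition,User of intravenous drugs,iv_drug_use,TRUE
infective_condition,Night pain,night_pain,TRUE
inflammatory_condition,Age,age,TRUE
inflammatory_condition,Waking at night,sleep_disturbance,FALSE
inflammatory_condition,Improvement with movement,,FALSE
inflammatory_condition,Improvement with NSAIDs,nsaid_improvement,FALSE
inflammatory_condition,"Past enthesitis, psoriasis, or arthritis",past_enthesitis_psoriasis_arthritis,TRUE
inflammatory_condition,Uveitis,uveitis_or_ibd,TRUE
inflammatory_condition,Inflammatory bowel disease,uveitis_or_ibd,TRUE
nerve_root_condition,Unilateral leg pain,,FALSE
nerve_root_condition,Dermatomal changes,,FALSE
nerve_root_condition,Myotomal weakness,myotomal_weakness,TRUE
nerve_root_condition,Straight leg raise test positive,,FALSE
nerve_root_condition,Age,age,FALSE
nerve_root_condition,Smoking,,FALSE
nerve_root_condition,Obesity,,FALSE
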