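criterion_id,intervention,score_mean,score_sd
disease_severity,Saxagliptin,4.00,1.26
disease_severity,Alogliptin,4.00,1.26
disease_severity,Sitagliptin,4.00,1.26
disease_severity,Linagliptin,4.00,1.26
disease_severity,Vildagliptin,4.00,1.26
size_of_affected_population,Saxagliptin,4.33,0.52
size_of_affected_population,Alogliptin,4.33,0.52
size_of_affected_population,Sitagliptin,4.33,0.52
size_of_affected_population,Linagliptin,4.33,0.52
size_of_affected_population,Vildagliptin,4.33,0.52
unmet_needs,Saxagliptin,3.50,0.55
unmet_needs,Alogliptin,3.50,0.55
unmet_needs,Sitagliptin,3.50,0.55
unmet_needs,Linagliptin,3.50,0.55
unmet_needs,Vildagliptin,3.50,0.55
comparative_effectiveness,Saxagliptin,3.50,1.64
comparative_effectiveness,Alogliptin,4.33,1.03
comparative_effectiveness,Sitagliptin,4.67,0.52
comparative_effectiveness,Linagliptin,4.33,1.03
comparative_effectiveness,Vildagliptin,3.67,1.51
comparative_safety_tolerability,Saxagliptin,0.17,0.98
comparative_safety_tolerability,Alogliptin,0.33,0.82
comparative_safety_tolerability,Sitagliptin,0.83,0.75
comparative_safety_tolerability,Linagliptin,0.67,1.21
comparative_safety_tolerability,Vildagliptin,0.67,0.82
patient_perceived_health_pro,Saxagliptin,-0.17,0.41
patient_perceived_health_pro,Alogliptin,-0.33,0.52
patient_perceived_health_pro,Sitagliptin,-0.17,0.41
patient_perceived_health_pro,Linagliptin,-0.17,0.41
patient_perceived_health_pro,Vildagliptin,-0.50,0.55
type_of_therapeutic_benefit,Saxagliptin,4.00,0.00
type_of_therapeutic_benefit,Alogliptin,4.00,0.00
type_of_therapeutic_benefit,Sitagliptin,4.00,0.00
type_of_therapeutic_benefit,Linagliptin,4.00,0.00
type_of_therapeutic_benefit,Vildagliptin,4.00,0.00
type_of_preventive_benefit,Saxagliptin,,
type_of_preventive_benefit,Alogliptin,,
type_of_preventive_benefit,Sitagliptin,,
type_of_preventive_benefit,Linagliptin,,
type_of_preventive_benefit,Vildagliptin,,
cost_of_intervention,Saxagliptin,-1.83,1.33
cost_of_intervention,Alogliptin,-1.83,1.33
cost_of_intervention,Sitagliptin,-1.50,0.84
cost_of_intervention,Linagliptin,-1.33,0.82
cost_of_intervention,Vildagliptin,-1.17,0.98
other_medical_costs,Saxagliptin,,
other_medical_costs,Alogliptin,,
other_medical_costs,Sitagliptin,,
other_medical_costs,Linagliptin,,
other_medical_costs,Vildagliptin,,
non_medical_costs,Saxagliptin,-1.83,1.47
non_medical_costs,Alogliptin,-1.67,1.51
non_medical_costs,Sitagliptin,-1.33,1.03
non_medical_costs,Linagliptin,-1.50,1.05
non_medical_costs,Vildagliptin,-1.33,1.21
quality_of_evidence,Saxagliptin,3.33,0.82
quality_of_evidence,Alogliptin,3.33,0.82
quality_of_evidence,Sitagliptin,3.33,0.82
quality_of_evidence,Linagliptin,3.33,0.82
quality_of_evidence,Vildagliptin,3.33,0.82
expert_consensus_guidelines,Saxagliptin,3.67,1.51
expert_consensus_guidelines,Alogliptin,3.67,1.51
expert_consensus_guidelines,Sitagliptin,3.67,1.51
expert_consensus_guidelines,Linagliptin,3.67,1.51
expert_consensus_guidelines,Vildagliptin,3.67,1.51
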