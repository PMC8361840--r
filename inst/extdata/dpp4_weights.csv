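criterion_id,weight_mean,weight_sd
disease_severity,3.58,0.75
size_of_affected_population,3.58,0.75
unmet_needs,3.01,0.55
comparative_effectiveness,3.73,0.82
comparative_safety_tolerability,3.58,0.98
patient_perceived_health_pro,3.44,0.63
type_of_therapeutic_benefit,3.58,1.17
cost_of_intervention,3.58,0.75
other_medical_costs,3.30,0.98
non_medical_costs,2.87,1.03
quality_of_evidence,4.01,0.52
expert_consensus_guidelines,3.44,0.63
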