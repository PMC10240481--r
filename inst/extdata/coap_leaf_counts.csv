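leaf_id,count
epi_case_report,241
epi_case_series,350
epi_case_control_study,74
epi_cohort_study,246
epi_cross_sectional_study,284
epi_diagnostic_study,181
epi_ecological_study,92
epi_guidelines,326
epi_modelling_study,808
epi_other,130
epi_outbreak_surveillance_report,133
epi_qualitative_study,35
epi_review,725
epi_trial,40
basic_animal_experiment,43
basic_research_review,135
basic_biochem_protein_structure,264
basic_in_vitro_experiment,85
basic_sequencing_phylogenetics,241
basic_within_host_modelling,31
other_other,143
other_comment_editorial,1758
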