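{
  "name": "COAP study-design taxonomy",
  "description": "Two classes, three subclasses, 22 mutually exclusive sub-subclasses describing publication study design or article type for living systematic review triage.",
  "nodes": [
    {"id": "original", "name": "ORIGINAL", "level": "class"},
    {"id": "non_original", "name": "NON-ORIGINAL", "level": "class"},
    {"id": "epi", "name": "EPI", "level": "subclass", "parent": "original"},
    {"id": "basic", "name": "BASIC", "level": "subclass", "parent": "original"},
    {"id": "other", "name": "OTHER", "level": "subclass", "parent": "non_original"},
    {"id": "epi_case_report", "name": "EPI: Case report", "level": "sub-subclass", "parent": "epi"},
    {"id": "epi_case_series", "name": "EPI: Case series", "level": "sub-subclass", "parent": "epi"},
    {"id": "epi_case_control_study", "name": "EPI: Case-control study", "level": "sub-subclass", "parent": "epi"},
    {"id": "epi_cohort_study", "name": "EPI: Cohort study", "level": "sub-subclass", "parent": "epi"},
    {"id": "epi_cross_sectional_study", "name": "EPI: Cross-sectional study", "level": "sub-subclass", "parent": "epi"},
    {"id": "epi_diagnostic_study", "name": "EPI: Diagnostic study", "level": "sub-subclass", "parent": "epi"},
    {"id": "epi_ecological_study", "name": "EPI: Ecological study", "level": "sub-subclass", "parent": "epi"},
    {"id": "epi_guidelines", "name": "EPI: Guidelines", "level": "sub-subclass", "parent": "epi"},
    {"id": "epi_modelling_study", "name": "EPI: Modelling study", "level": "sub-subclass", "parent": "epi"},
    {"id": "epi_other", "name": "EPI: Other", "level": "sub-subclass", "parent": "epi"},
    {"id": "epi_outbreak_surveillance_report", "name": "EPI: Outbreak or surveillance report", "level": "sub-subclass", "parent": "epi"},
    {"id": "epi_qualitative_study", "name": "EPI: Qualitative study", "level": "sub-subclass", "parent": "epi"},
    {"id": "epi_review", "name": "EPI: Review", "level": "sub-subclass", "parent": "epi"},
    {"id": "epi_trial", "name": "EPI: Trial", "level": "sub-subclass", "parent": "epi"},
    {"id": "basic_animal_experiment", "name": "BASIC: Animal experiment", "level": "sub-subclass", "parent": "basic"},
    {"id": "basic_research_review", "name": "BASIC: Basic research review", "level": "sub-subclass", "parent": "basic"},
    {"id": "basic_biochem_protein_structure", "name": "BASIC: Biochemical/protein structure studies", "level": "sub-subclass", "parent": "basic"},
    {"id": "basic_in_vitro_experiment", "name": "BASIC: In vitro experiment", "level": "sub-subclass", "parent": "basic"},
    {"id": "basic_sequencing_phylogenetics", "name": "BASIC: Sequencing and phylogenetics", "level": "sub-subclass", "parent": "basic"},
    {"id": "basic_within_host_modelling", "name": "BASIC: Within-host modelling", "level": "sub-subclass", "parent": "basic", "alias": "BASIC: Within-host modeling"},
    {"id": "other_other", "name": "OTHER: Other", "level": "sub-subclass", "parent": "other"},
    {"id": "other_comment_editorial", "name": "OTHER: Comment, editorial, ..., non-original", "level": "sub-subclass", "parent": "other"}
  ]
}
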