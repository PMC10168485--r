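category,n_all,mean_age_all,n_twins_removed,mean_age_twins_removed
OlderNormal,53,61.30,49,61.37
Metabolic,66,66.48,62,66.26
Sensory,7,68.14,7,68.14
Unclassified,19,67.32,17,66.65
Unselected,14,65.29,13,65.15
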