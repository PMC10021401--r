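# schema: u5mproj/scenario_targets v1
factor,higher_is_better,baseline_2014_pct,target_2022_pct,target_2025_pct
anc4,TRUE,57.7,70,80
antimalarial,TRUE,33.5,70,90
early_breastfeeding,TRUE,62.8,70,80
sanitation,TRUE,90.1,65,70
facility_delivery,TRUE,61.5,73,75
fever_treatment,TRUE,72.8,80,90
hiv,FALSE,5,3.3,2.8
itn_use,TRUE,56,80,95
fully_immunised,TRUE,78.8,80,85
water,TRUE,63.4,78,80
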