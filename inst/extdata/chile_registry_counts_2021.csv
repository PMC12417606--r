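key,value
registry_total,3056306
boys_total,1569082
girls_total,1487224
pie_total,339968
asd_total,14549
asd_boys,12571
asd_girls,1978
schools_total,12077
clinical_population,132242
clinical_seed_accessors,488
clinical_unmatched_patients,1132
clinical_matches,233
clinical_blocked_pairs,293
national_school_adjusted_pct,0.46
national_school_adjusted_lo,0.45
national_school_adjusted_hi,0.47
clinical_school_adjusted_pct,0.37
clinical_school_adjusted_lo,0.34
clinical_school_adjusted_hi,0.41
clinical_updated_adjusted_pct,1.22
clinical_updated_adjusted_lo,1.16
clinical_updated_adjusted_hi,1.28
national_posited_cases,40113
national_unmet_cases,25903
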