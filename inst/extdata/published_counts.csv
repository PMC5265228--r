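quantifier,rule,calibrated,mode,false_positives,false_negatives,printed_sensitivity,printed_specificity,sensitivity_consistent,specificity_consistent
small_voi,striatum_either_side,TRUE,ACSC,5,7,83.7,85.3,TRUE,TRUE
small_voi,striatum_either_side,TRUE,IRNC,6,6,86.1,82.4,FALSE,TRUE
small_voi,striatum_either_side,TRUE,FBP,7,7,83.7,79.4,TRUE,TRUE
small_voi,striatum_either_side,FALSE,ACSC,5,9,79.1,85.3,TRUE,TRUE
small_voi,striatum_either_side,FALSE,IRNC,3,14,67.4,91.2,TRUE,TRUE
small_voi,striatum_either_side,FALSE,FBP,4,11,74.4,88.2,TRUE,TRUE
small_voi,putamen_either_side,TRUE,ACSC,6,7,83.7,82.4,TRUE,TRUE
small_voi,putamen_either_side,TRUE,IRNC,5,7,83.7,85.3,TRUE,TRUE
small_voi,putamen_either_side,TRUE,FBP,7,8,81.4,79.4,TRUE,TRUE
small_voi,putamen_either_side,FALSE,ACSC,5,7,83.7,85.3,TRUE,TRUE
small_voi,putamen_either_side,FALSE,IRNC,3,10,76.7,91.2,TRUE,TRUE
small_voi,putamen_either_side,FALSE,FBP,4,8,81.4,88.2,TRUE,TRUE
large_voi,southampton_striatal,TRUE,ACSC,6,4,90.7,82.4,TRUE,TRUE
large_voi,southampton_striatal,TRUE,IRNC,6,10,76.7,82.4,TRUE,TRUE
large_voi,southampton_striatal,TRUE,FBP,6,14,67.4,82.4,TRUE,TRUE
large_voi,southampton_striatal,FALSE,ACSC,4,14,65.1,88.2,FALSE,TRUE
large_voi,southampton_striatal,FALSE,IRNC,4,14,67.4,88.2,TRUE,TRUE
large_voi,southampton_striatal,FALSE,FBP,4,17,60.5,88.2,TRUE,TRUE
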