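quantity,count,description
vl_available_week16,160,participants with an HIV-RNA inside the week-16 window (weeks 12-20)
suppressed_week16,146,of these suppressed to <=400 copies/ml
vl_available_week48,180,participants with an HIV-RNA inside the week-48 window (weeks 32-64)
suppressed_week48,153,of these suppressed to <=40 copies/ml
dosing_days_total,82311,participant dosing days recorded by the electronic monitor
dead_battery_days,8362,censored dead-battery days among them
genotyped_week16,12,successfully amplified genotypes at week 16
k65r_week16,8,week-16 genotypes carrying K65R
genotyped_week48,11,successfully amplified genotypes at week 48
m184v_week48,4,week-48 genotypes carrying M184V
in_care,186,participants in care at study site at end of study
transferred,16,transferred care elsewhere
died,8,died during the study
ltfu,19,lost to follow-up (>12 weeks without visit)
withdrew,1,withdrew consent
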