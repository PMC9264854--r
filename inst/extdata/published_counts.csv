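characteristic,level,screened,not_screened
age,15-34,78480,381477
age,35-49,68900,170829
bmi,underweight,22438,128221
bmi,normal,83587,326849
bmi,overweight,29397,67719
bmi,obese,9868,19077
facility,not_a_big_problem,97774,343517
facility,distance_only,10596,39800
facility,transport_only,7468,29876
facility,distance_and_transport,31542,139113
contraception,condom,9458,20059
contraception,others,70756,160985
contraception,none,67166,371262
children,none,15075,207992
children,one_or_two,74678,176906
children,three_or_four,44925,120985
children,more_than_four,12702,46423
autonomy,alone,2865,6573
autonomy,with_husband,16976,39262
autonomy,husband_or_family,6009,15126
sex_partners,one,25482,59624
sex_partners,two,475,1311
sex_partners,more_than_two,239,747
sti,no,4809,23468
sti,yes,23127,70947
religion,hindu,109376,409905
religion,muslim,19247,75344
religion,christian,9454,42659
religion,others,9303,24398
wealth,poorest,18224,115025
wealth,poorer,25994,123472
wealth,middle,30999,116169
wealth,richer,33826,104676
wealth,richest,38337,92964
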