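column,role,type,units_or_levels,description
id,identifier,character,,opaque row identifier
family_income_cat,base_confounder,categorical,"lt1|1to3|3to6|6to10|gt10",family income at birth in minimum wages
household_score,base_confounder,continuous,score,household goods score index
maternal_schooling_cat,base_confounder,categorical,"0to4|5to8|9to11|ge12",maternal schooling in completed years
maternal_smoking,base_confounder,binary,0/1,maternal smoking during pregnancy
birthweight_g,base_confounder,continuous,grams,birthweight
breastfeeding_cat,base_confounder,categorical,"lt1|1to3|3to6|6to9|9to12|ge12",breastfeeding duration in months
african_ancestry,base_confounder,continuous,proportion 0-1,African genomic-ancestry proportion
menarche_cat,exposure,categorical,"lt12|mid|ge14",age at menarche: <12 / 12-13 / >=14 years
active,post_confounder,binary,0/1,leisure-time + commuting physical activity >=150 min/week
saturated_fat_pct,post_confounder,continuous,percent,% saturated fat in diet (calorie-adjusted)
bmi,mediator,continuous,kg/m2,body mass index
fat_mass_index,mediator,continuous,kg/m2,DXA fat mass / height squared
waist_hip_ratio,mediator,continuous,ratio x100,waist-to-hip circumference ratio times 100
sbp,outcome,continuous,mmHg,systolic blood pressure
dbp,outcome,continuous,mmHg,diastolic blood pressure
total_chol,outcome,continuous,mg/dl,total cholesterol
hdl,outcome,continuous,mg/dl,HDL cholesterol
ldl,outcome,continuous,mg/dl,LDL cholesterol
triglycerides,outcome,continuous,mg/dl (log-normal),triglycerides
glucose,outcome,continuous,mg/dl,plasma glucose
hba1c,outcome,continuous,percent,glycated haemoglobin
crp,outcome,continuous,mg/dl (log-normal),C-reactive protein
cimt,outcome,continuous,micrometre,carotid intima-media thickness
pwv,outcome,continuous,m/s,pulse wave velocity
pregnant,flag,binary,0/1,pregnant at assessment
postpartum_3m,flag,binary,0/1,three months or less postpartum
oral_contraceptive,flag,binary,0/1,oral contraceptive use
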