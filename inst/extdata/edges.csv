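"source","target","capacity","probability"
"Entrance","Emergency Department",5,0.476190476190476
"Entrance","Infectious diseases Unit",5,0.0952380952380952
"Entrance","Medical Ward",5,0.142857142857143
"Entrance","Cardiac",5,0.0952380952380952
"Entrance","Maternity",5,0.0952380952380952
"Entrance","Psychiatry",5,0.0476190476190476
"Entrance","Pediatrics",5,0.0476190476190476
"Emergency Department","Medical Ward",5,0.166666666666667
"Emergency Department","Cardiac",5,0.125
"Emergency Department","Respiratory",5,0.0833333333333333
"Emergency Department","Surgery",5,0.125
"Emergency Department","Orthopedics",5,0.0833333333333333
"Emergency Department","ICU",5,0.0833333333333333
"Emergency Department","Neurology",5,0.0833333333333333
"Emergency Department","Urology",5,0.0416666666666667
"Emergency Department","Discharge",5,0.208333333333333
"Infectious diseases Unit","Medical Ward",5,0.25
"Infectious diseases Unit","Respiratory",5,0.125
"Infectious diseases Unit","ICU",5,0.125
"Infectious diseases Unit","Discharge",5,0.5
"Medical Ward","Cardiac",5,0.0833333333333333
"Medical Ward","Respiratory",5,0.0833333333333333
"Medical Ward","Oncology",5,0.0833333333333333
"Medical Ward","Geriatrics",5,0.166666666666667
"Medical Ward","Radiology",5,0.0833333333333333
"Medical Ward","Laboratory",5,0.0833333333333333
"Medical Ward","Discharge",5,0.416666666666667
"Cardiac","ICU",5,0.25
"Cardiac","Radiology",5,0.125
"Cardiac","Rehabilitation",5,0.125
"Cardiac","Discharge",5,0.5
"Respiratory","ICU",5,0.2
"Respiratory","Laboratory",5,0.2
"Respiratory","Discharge",5,0.6
"Surgery","ICU",5,0.25
"Surgery","Orthopedics",5,0.125
"Surgery","Rehabilitation",5,0.25
"Surgery","Discharge",5,0.375
"Orthopedics","Radiology",5,0.166666666666667
"Orthopedics","Rehabilitation",5,0.333333333333333
"Orthopedics","Discharge",5,0.5
"ICU","Rehabilitation",5,0.25
"ICU","Geriatrics",5,0.25
"ICU","Discharge",5,0.5
"Pediatrics","Respiratory",5,0.2
"Pediatrics","Laboratory",5,0.2
"Pediatrics","Discharge",5,0.6
"Maternity","Pediatrics",5,0.2
"Maternity","Discharge",5,0.8
"Oncology","Radiology",5,0.2
"Oncology","Laboratory",5,0.2
"Oncology","Discharge",5,0.6
"Neurology","Radiology",5,0.2
"Neurology","Rehabilitation",5,0.2
"Neurology","Discharge",5,0.6
"Geriatrics","Rehabilitation",5,0.2
"Geriatrics","Discharge",5,0.8
"Radiology","Discharge",5,1
"Laboratory","Discharge",5,1
"Rehabilitation","Discharge",5,1
"Psychiatry","Discharge",5,1
"Urology","Discharge",5,1
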