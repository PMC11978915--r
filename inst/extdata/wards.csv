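"ward","beds","staff"
"Emergency Department",30,30
"Infectious diseases Unit",15,15
"Medical Ward",40,40
"Cardiac",20,20
"Respiratory",18,18
"Surgery",25,25
"Orthopedics",22,22
"ICU",12,12
"Pediatrics",20,20
"Maternity",16,16
"Oncology",24,24
"Neurology",18,18
"Geriatrics",28,28
"Radiology",8,8
"Laboratory",6,6
"Rehabilitation",30,30
"Psychiatry",20,20
"Urology",12,12
"Entrance",1e+09,1e+09
"Discharge",1e+09,1e+09
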