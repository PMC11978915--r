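"ward","los_hours"
"Emergency Department",1
"Emergency Department",2
"Emergency Department",3
"Emergency Department",4
"Emergency Department",6
"Emergency Department",8
"Emergency Department",12
"Infectious diseases Unit",48
"Infectious diseases Unit",72
"Infectious diseases Unit",120
"Infectious diseases Unit",168
"Infectious diseases Unit",240
"Medical Ward",24
"Medical Ward",48
"Medical Ward",72
"Medical Ward",96
"Medical Ward",144
"Cardiac",24
"Cardiac",48
"Cardiac",96
"Cardiac",120
"Respiratory",24
"Respiratory",48
"Respiratory",72
"Respiratory",120
"Surgery",12
"Surgery",24
"Surgery",48
"Surgery",96
"Orthopedics",24
"Orthopedics",48
"Orthopedics",72
"Orthopedics",120
"ICU",24
"ICU",48
"ICU",96
"ICU",168
"ICU",240
"Pediatrics",12
"Pediatrics",24
"Pediatrics",48
"Pediatrics",72
"Maternity",24
"Maternity",48
"Maternity",72
"Oncology",48
"Oncology",96
"Oncology",168
"Oncology",240
"Neurology",24
"Neurology",72
"Neurology",120
"Neurology",168
"Geriatrics",72
"Geriatrics",120
"Geriatrics",240
"Geriatrics",360
"Radiology",0.5
"Radiology",1
"Radiology",1.5
"Radiology",2
"Laboratory",0.25
"Laboratory",0.5
"Laboratory",1
"Rehabilitation",120
"Rehabilitation",240
"Rehabilitation",360
"Rehabilitation",504
"Psychiatry",72
"Psychiatry",168
"Psychiatry",336
"Urology",12
"Urology",24
"Urology",48
"Urology",72
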