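"ae_name","arm","affected","total","grade","item_cost","recurring"
"diarrhea","cabozantinib",254,470,"1-2",24.06,TRUE
"diarrhea","cabozantinib",254,470,"3-4",477.4,FALSE
"diarrhea","BSC",45,237,"1-2",21.07,TRUE
"diarrhea","BSC",45,237,"3-4",231.73,FALSE
"hand_foot_syndrome","cabozantinib",216,470,"1-2",63.1,TRUE
"hand_foot_syndrome","cabozantinib",216,470,"3-4",28.29,FALSE
"hand_foot_syndrome","BSC",12,237,"1-2",39.5,TRUE
"hand_foot_syndrome","BSC",12,237,"3-4",19.75,FALSE
"fatigue","cabozantinib",212,470,"1-2",33.25,TRUE
"fatigue","BSC",71,237,"1-2",30.04,TRUE
"nausea_vomiting","cabozantinib",207,470,"1-2",102.17,TRUE
"nausea_vomiting","cabozantinib",207,470,"3-4",108.99,FALSE
"nausea_vomiting","BSC",62,237,"1-2",99.39,TRUE
"nausea_vomiting","BSC",62,237,"3-4",145.26,FALSE
"hypertension","cabozantinib",141,470,"1-2",40,TRUE
"hypertension","cabozantinib",141,470,"3-4",16.67,FALSE
"hypertension","BSC",14,237,"1-2",16.93,TRUE
"hypertension","BSC",14,237,"3-4",16.93,FALSE
"abdominal_pain","cabozantinib",118,470,"3-4",95.59,FALSE
"abdominal_pain","BSC",50,237,"3-4",194.34,FALSE
"stomatitis","cabozantinib",103,470,"1-2",18.25,TRUE
"stomatitis","BSC",5,237,"1-2",47.4,TRUE
"rash","cabozantinib",99,470,"1-2",75.96,TRUE
"rash","BSC",12,237,"1-2",98.75,TRUE
"thrombocytopenia","cabozantinib",118,470,"3-4",127.46,FALSE
"dyspepsia","cabozantinib",56,470,"3-4",16.79,FALSE
"dyspepsia","BSC",12,237,"3-4",19.75,FALSE
"hypokalemia","cabozantinib",85,470,"1-2",5.53,TRUE
"hypokalemia","cabozantinib",85,470,"3-4",481.06,FALSE
"hypokalemia","BSC",14,237,"1-2",8.46,TRUE
"hypokalemia","BSC",14,237,"3-4",397.82,FALSE
"pain_in_extremity","cabozantinib",42,470,"3-4",22.38,FALSE
"pain_in_extremity","BSC",12,237,"3-4",19.75,FALSE
"hypothyroidism","cabozantinib",99,470,"1-2",2.37,TRUE
"hypothyroidism","cabozantinib",99,470,"3-4",59.34,FALSE
"hypothyroidism","BSC",2,237,"1-2",29.63,TRUE
"hypothyroidism","BSC",2,237,"3-4",29.63,FALSE
"hypomagnesemia","cabozantinib",52,470,"3-4",298.27,FALSE
"urinary_tract_infection","cabozantinib",33,470,"3-4",370.3,FALSE
"urinary_tract_infection","BSC",9,237,"3-4",289.67,FALSE
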