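scope,indicator,n_df,prev_df,se_df,deft_df,n_sf,prev_sf,se_sf,deft_sf,rel_diff
all,poor_health,25319,6.0,0.2,1.30,15602,5.7,0.2,1.21,-5.0
all,chronic_disease,25319,36.6,0.4,1.22,15602,36.3,0.4,1.13,-0.8
all,activity_limitation,25319,21.6,0.3,1.23,15602,21.1,0.4,1.15,-2.4
all,obesity,25319,13.5,0.3,1.27,15602,13.1,0.3,1.17,-3.2
all,physical_inactivity,25319,8.7,0.2,1.32,15602,8.9,0.3,1.20,2.0
all,daily_smoking,25319,27.0,0.4,1.28,15602,27.6,0.4,1.14,2.4
all,suicide_attempt,25319,7.2,0.2,1.28,15602,7.4,0.2,1.15,2.4
18-30,poor_health,4452,1.9,0.3,NA,3503,2.1,0.3,NA,7.8
18-30,chronic_disease,4452,20.8,0.7,NA,3503,22.1,0.8,NA,6.0
18-30,activity_limitation,4452,10.6,0.6,NA,3503,10.9,0.6,NA,3.0
18-30,obesity,4452,6.9,0.5,NA,3503,7.2,0.5,NA,4.3
18-30,physical_inactivity,4452,6.9,0.5,NA,3503,6.1,0.5,NA,-11.9
18-30,daily_smoking,4452,34.5,0.9,NA,3503,35.5,0.9,NA,2.9
18-30,suicide_attempt,4452,6.4,0.5,NA,3503,6.7,0.5,NA,3.9
60-75,poor_health,7226,8.7,0.4,NA,3161,8.1,0.6,NA,-6.7
60-75,chronic_disease,7226,52.9,0.7,NA,3161,52.5,1.0,NA,-0.9
60-75,activity_limitation,7226,31.2,0.7,NA,3161,30.1,0.9,NA,-3.5
60-75,obesity,7226,18.2,0.6,NA,3161,16.8,0.8,NA,-7.9
60-75,physical_inactivity,7226,8.9,0.4,NA,3161,9.5,0.6,NA,5.9
60-75,daily_smoking,7226,12.3,0.5,NA,3161,13.4,0.7,NA,8.7
60-75,suicide_attempt,7226,6.2,0.3,NA,3161,6.7,0.5,NA,8.2
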