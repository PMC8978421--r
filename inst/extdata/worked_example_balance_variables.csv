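block,variable,D_df,D_sf
calibration,sex,5.6,3.0
calibration,age,2.0,2.7
calibration,education,10.3,13.1
calibration,hh_size,7.4,5.0
calibration,urbanization,2.6,2.5
calibration,region,1.7,1.7
external,professional_status,8.0,7.8
external,socio_professional_group,2.9,2.8
external,family_physician_visit,6.6,8.2
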