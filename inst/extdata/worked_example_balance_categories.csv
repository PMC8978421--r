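block,variable,category,ref_share_pct,d_df,d_sf
calibration,sex,male,48.7,-5.6,-3.0
calibration,sex,female,51.3,5.6,3.0
calibration,age,18-24,11.2,-2.3,1.3
calibration,age,25-34,17.1,0.5,5.2
calibration,age,35-44,18.5,-2.3,0.8
calibration,age,45-54,19.5,-1.5,-0.3
calibration,age,55-64,18.2,2.6,0.5
calibration,age,65-75,15.5,2.7,-8.1
calibration,education,primary,13.3,-19.8,-22.9
calibration,education,less_than_high_school,35.4,-8.9,-14.6
calibration,education,high_school,20.4,3.2,5.6
calibration,education,post_secondary_2y,12.8,-0.6,1.8
calibration,education,post_secondary_3_4y,7.6,22.4,24.1
calibration,education,post_secondary_5y_plus,10.5,6.6,9.5
calibration,hh_size,1,17.4,14.7,12.3
calibration,hh_size,2,34.2,2.5,-2.3
calibration,hh_size,3,18.9,-6.0,-2.3
calibration,hh_size,4,19.3,-8.4,-5.4
calibration,hh_size,5+,10.2,-5.5,-2.7
calibration,urbanization,rural,24.0,2.3,-2.8
calibration,urbanization,lt_20k,16.8,-0.8,-1.9
calibration,urbanization,20k_100k,12.1,2.1,1.8
calibration,urbanization,100k_200k,4.9,4.4,4.8
calibration,urbanization,ge_200k,25.7,-4.2,-1.4
calibration,urbanization,paris,16.6,-1.9,2.1
calibration,region,IDF,19.0,-2.8,1.6
calibration,region,Grand-Est,8.6,-0.4,-1.9
calibration,region,Hauts-de-France,9.3,-2.5,-2.4
calibration,region,Normandie,5.1,1.3,-0.8
calibration,region,Centre,4.0,-1.0,-2.1
calibration,region,Bourgogne-FC,4.4,-0.5,-1.7
calibration,region,Bretagne,5.1,3.9,3.2
calibration,region,Pays-de-Loire,5.7,-0.9,-2.6
calibration,region,Nouvelle-Aquitaine,9.2,1.0,0.9
calibration,region,ARA,12.2,3.0,1.8
calibration,region,Occitanie,9.1,1.4,1.5
calibration,region,PACA-Corse,8.3,-1.5,0.2
external,professional_status,employed,58.7,-6.1,-4.3
external,professional_status,student,5.0,9.2,8.0
external,professional_status,unemployed,6.2,11.6,12.0
external,professional_status,retired_inactive,30.2,-5.3,-6.9
external,socio_professional_group,farmer,1.7,0.8,0.8
external,socio_professional_group,craftsperson,6.3,0.0,2.4
external,socio_professional_group,executive,17.2,-7.1,-6.3
external,socio_professional_group,intermediate,25.1,-1.9,-1.9
external,socio_professional_group,technician,27.9,3.1,2.7
external,socio_professional_group,blue_collar,21.8,4.5,3.1
external,family_physician_visit,yes,85.5,-6.6,-8.2
external,family_physician_visit,no,14.5,6.6,8.2
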