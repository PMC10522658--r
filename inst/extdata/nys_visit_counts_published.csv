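cause,group,level,count
alcohol,total,total,671625
substance,total,total,721469
cannabis,total,total,139240
cocaine,total,total,228989
opioids,total,total,275707
sedatives,total,total,50068
alcohol,age,0-24,58320
alcohol,age,25-44,310415
alcohol,age,45-64,271144
alcohol,age,65+,31746
substance,age,0-24,120077
substance,age,25-44,373214
substance,age,45-64,209459
substance,age,65+,18719
cannabis,age,0-24,52307
cannabis,age,25-44,65870
cannabis,age,45-64,20534
cannabis,age,65+,529
cocaine,age,0-24,20097
cocaine,age,25-44,139053
cocaine,age,45-64,68280
cocaine,age,65+,1559
opioids,age,0-24,34964
opioids,age,25-44,145307
opioids,age,45-64,89615
opioids,age,65+,5821
sedatives,age,0-24,5740
sedatives,age,25-44,24812
sedatives,age,45-64,17203
sedatives,age,65+,2313
alcohol,sex,female,246404
alcohol,sex,male,425221
substance,sex,female,303549
substance,sex,male,417920
cannabis,sex,female,55322
cannabis,sex,male,83918
cocaine,sex,female,89734
cocaine,sex,male,139255
opioids,sex,female,116180
opioids,sex,male,159527
sedatives,sex,female,23469
sedatives,sex,male,26599
alcohol,admission_type,inpatient,510449
alcohol,admission_type,outpatient,161176
substance,admission_type,inpatient,535334
substance,admission_type,outpatient,186135
cannabis,admission_type,inpatient,94756
cannabis,admission_type,outpatient,44484
cocaine,admission_type,inpatient,191250
cocaine,admission_type,outpatient,37739
opioids,admission_type,inpatient,229442
opioids,admission_type,outpatient,46265
sedatives,admission_type,inpatient,43352
sedatives,admission_type,outpatient,6716
alcohol,location,in_city,261944
alcohol,location,not_in_city,409681
substance,location,in_city,305900
substance,location,not_in_city,415569
cannabis,location,in_city,45986
cannabis,location,not_in_city,93254
cocaine,location,in_city,108318
cocaine,location,not_in_city,120671
opioids,location,in_city,129607
opioids,location,not_in_city,146100
sedatives,location,in_city,21799
sedatives,location,not_in_city,28269
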