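block,category,F1,F2,F3,F4,F5
gender,Male,7,8,10,6,3
gender,Female,12,17,6,0,1
age,< 40,4,13,12,1,3
age,40-60,7,4,3,3,1
age,60+,8,8,1,2,0
mean_age,mean,55,43,34,52,30
education,Under high school,3,6,3,1,0
education,High school,4,1,2,1,0
education,Secondary specialised,3,1,1,3,1
education,College,3,4,2,1,1
education,University,6,13,8,0,2
eq5d_profile,11111,8,7,8,4,0
eq5d_profile,11112,2,3,2,0,0
eq5d_profile,11121,3,5,1,0,1
eq5d_profile,11122,1,3,2,2,1
eq5d_profile,Other,5,6,3,0,2
vas_band,80-100,10,17,9,3,3
vas_band,60-80,8,4,7,3,1
vas_band,< 60,1,3,0,0,0
residence,City,12,13,10,2,3
residence,Non-city,7,12,6,4,1
region,Southwest China,13,12,4,3,1
region,East China,5,4,7,3,2
region,North China,0,5,4,0,1
region,Other,1,4,1,0,0
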