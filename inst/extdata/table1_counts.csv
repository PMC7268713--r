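block,category,count
gender,Male,57
gender,Female,53
age,< 40,44
age,40-60,35
age,60+,31
education,Under high school,20
education,High school,14
education,Secondary specialised,15
education,College,18
education,University,42
eq5d_profile,11111,42
eq5d_profile,11112,15
eq5d_profile,11121,16
eq5d_profile,11122,14
eq5d_profile,Other,22
vas_band,80-100,69
vas_band,60-80,35
vas_band,< 60,5
residence,City,63
residence,Non-city,47
region,Southwest China,54
region,East China,34
region,North China,13
region,Other,9
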