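participant_id,cohort_id,cohort_order,target_dose_min,achieved_dose_min,completed,nrs_t1,nrs_t2,nrs_t3,ppt_left_t1,ppt_left_t2,ppt_right_t1,ppt_right_t2,ownership,symptoms_24h
001,C1,1,2,2,TRUE,8,8,9,103.67,103.00,84.33,110.33,-3,Headache; neck pain; fatigue
002,C1,1,2,2,TRUE,3,3,4,163.00,162.33,142.33,157.67,3,
003,C1,1,2,2,TRUE,3,6,5,92.33,93.67,116.67,95.67,3,Headache; shoulder pain; fatigue
004,C2,2,4,4,TRUE,7,8,7,144.33,180.33,153.67,170.67,1,Headache; neck pain; fatigue
005,C2,2,4,4,TRUE,5,5,4,201.00,276.00,217.00,292.33,-3,
006,C2,2,4,4,TRUE,4,4,5,218.33,308.33,266.00,320.33,-2,Headache
007,C3,3,8,8,TRUE,7,7,8,220.33,192.33,108.33,160.00,1,Fatigue
008,C3,3,8,8,TRUE,4,3,3,341.33,408.67,249.33,315.67,-3,
009,C3,3,8,8,TRUE,5,3,3,72.00,101.00,62.67,113.33,-3,Headache
010,C4,4,16,16,TRUE,5,3,4,164.33,184.67,163.00,198.67,-2,
011,C4,4,16,16,TRUE,6,5,5,199.67,228.33,175.33,226.67,-2,Fatigue
012,C4,4,16,16,TRUE,5,4,7,119.33,140.00,98.00,138.33,-3,Headache; neck pain
013,C5,5,32,22.2,FALSE,5,5,4,243.00,261.67,348.67,351.67,-3,
014,C5,5,32,18.05,FALSE,5,5,6,427.33,369.33,343.33,364.67,0,Shoulder pain
015,C6,6,12,12,TRUE,6,5,4,58.00,66.67,51.67,75.00,-2,
016,C6,6,12,12,TRUE,8,6,5,27.67,29.00,23.33,28.33,-1,Headache; neck pain; fatigue
017,C6,6,12,12,TRUE,7,6,3,75.00,107.67,97.00,106.67,1,Stiffness; fatigue
018,C7,7,12,12,TRUE,7,4,1,115.00,123.00,156.67,162.67,-3,
019,C7,7,12,12,TRUE,3,1,7,72.00,62.67,83.00,60.33,3,Neck pain; fatigue
020,C7,7,12,12,TRUE,5,4,5,117.67,123.33,123.00,126.33,-3,Fatigue
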