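table,kind,id,n,count,percent,se,ci_low,ci_high
reliability,criterion,Identity,100,37,37.0,4.83,27.5,46.5
reliability,element,name,100,93,93.0,2.55,88.0,98.0
reliability,element,street_address,100,83,83.0,3.76,75.6,90.4
reliability,element,funding_sources,100,44,44.0,4.96,34.3,53.7
reliability,criterion,Purpose,100,52,52.0,5.00,42.2,61.8
reliability,element,purpose_mission,100,79,79.0,4.07,71.0,87.0
reliability,element,uses_limitations,100,82,82.0,3.84,74.5,89.5
reliability,element,commercial_association,100,71,71.0,4.54,62.1,79.9
reliability,criterion,ContentDevelopment,100,15,15.0,3.57,8.0,22.0
reliability,element,identify_advertising,60,28,46.7,6.44,34.0,59.3
reliability,element,editorial_policy,100,39,39.0,4.88,29.4,48.6
reliability,element,authorship,100,38,38.0,4.85,28.5,47.5
reliability,criterion,Privacy,100,83,83.0,3.76,75.6,90.4
reliability,element,privacy_policy,100,96,96.0,1.96,92.2,99.8
reliability,element,personal_info_protection,100,83,83.0,3.76,75.6,90.4
reliability,criterion,UserFeedback,100,90,90.0,3.00,84.1,95.9
reliability,element,feedback_mechanism,100,90,90.0,3.00,84.1,95.9
reliability,criterion,ContentUpdating,100,4,4.0,1.96,0.2,7.8
reliability,element,date_created,100,25,25.0,4.33,16.5,33.5
reliability,element,date_reviewed,100,28,28.0,4.49,19.2,36.8
usability,principle,1,100,78,78.0,4.14,69.9,86.1
usability,principle,2,100,68,68.0,4.66,58.9,77.1
usability,principle,3,100,24,24.0,4.27,15.6,32.4
usability,principle,4,100,100,100.0,0.00,100.0,100.0
usability,principle,5,99,39,39.4,4.91,29.8,49.0
usability,principle,6,100,6,6.0,2.37,1.3,10.7
usability,principle,7,100,30,30.0,4.58,21.0,39.0
usability,principle,8,100,70,70.0,4.58,61.0,79.0
usability,principle,9,100,30,30.0,4.58,21.0,39.0
usability,principle,10,100,42,42.0,4.94,32.3,51.7
usability,principle,11,100,17,17.0,3.76,9.6,24.4
usability,principle,12,100,25,25.0,4.33,16.5,33.5
usability,principle,13,100,45,45.0,4.97,35.2,54.8
usability,principle,14,100,72,72.0,4.49,63.2,80.8
usability,principle,15,100,45,45.0,4.97,35.2,54.8
usability,principle,16,100,74,74.0,4.39,65.4,82.6
usability,principle,17,100,30,30.0,4.58,21.0,39.0
usability,principle,18,100,32,32.0,4.66,22.9,41.1
usability,principle,19,100,19,19.0,3.92,11.3,26.7
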