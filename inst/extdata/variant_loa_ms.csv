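source,sensor,cutoff_hz,axis,bias,loa_lower,loa_upper,adj_printed
average,gyro,0,resultant,-2.8,-35.2,29.4,13.6
average,gyro,0,z,2.4,-29.8,34.4,12.8
average,gyro,0,y,9.4,-53.6,72.4,74.6
average,gyro,0,x,-7.6,-88.2,73.2,110
average,gyro,3,resultant,-5.4,-33.0,22.2,11.6
average,gyro,3,z,0.2,-28.0,28.6,6.6
average,gyro,3,y,5.8,-34.0,45.8,28.2
average,gyro,3,x,-10.6,-63.4,42.4,54.2
average,gyro,6,resultant,-3.2,-34.0,27.6,12.6
average,gyro,6,z,2.6,-29.2,34.4,12.0
average,gyro,6,y,8.2,-36.4,52.8,37.6
average,gyro,6,x,-9.4,-80.0,61.2,89.6
average,gyro,9,resultant,-3.2,-34.8,28.4,13.2
average,gyro,9,z,2.6,-29.8,35.0,13.2
average,gyro,9,y,12.2,-48.2,72.4,69.0
average,gyro,9,x,-9.2,-83.4,65.2,97.0
average,gyro,12,resultant,-3.4,-36.0,29.0,14.4
average,gyro,12,z,2.2,-31.2,35.6,15.4
average,gyro,12,y,12.2,-49.4,73.8,71.6
average,gyro,12,x,-8.8,-83.6,65.8,97.8
average,acc,0,resultant,-10.8,-79.6,58.0,86.0
average,acc,0,z,-29.8,NA,NA,NA
average,acc,0,y,-12.6,-42.2,16.8,20.6
average,acc,0,x,-111,NA,NA,NA
average,acc,3,resultant,-15.0,-79.4,49.6,77.4
average,acc,3,z,-5.0,-388,378,715
average,acc,3,y,-13.6,-40.0,12.6,18.4
average,acc,3,x,-57.4,NA,NA,NA
average,acc,6,resultant,-9.8,-32.0,12.4,10.6
average,acc,6,z,-4.2,-371,362,681
average,acc,6,y,-13.8,-40.4,12.6,19.0
average,acc,6,x,-62.8,NA,NA,NA
average,acc,9,resultant,-11.0,-12.4,57.6,85.6
average,acc,9,z,-12.4,-362,337,648
average,acc,9,y,-13.8,-41.8,14.2,20.2
average,acc,9,x,-65.2,NA,NA,NA
average,acc,12,resultant,-10.4,-79.8,59.0,87.2
average,acc,12,z,-19.8,-350,310,609
average,acc,12,y,-12.8,-42.4,16.6,20.8
average,acc,12,x,-67.0,NA,NA,NA
right,gyro,0,resultant,-5.0,-39.4,29.4,18.0
right,gyro,0,z,-0.8,-35.6,34.0,18.2
right,gyro,0,y,-0.2,-67.6,67.0,83.2
right,gyro,0,x,7.6,-163,178,290
right,gyro,3,resultant,-5.2,-36.8,28.2,15.2
right,gyro,3,z,0.4,-32.0,32.8,13.2
right,gyro,3,y,4.8,-40.6,50.2,39.4
right,gyro,3,x,4.0,-91.2,99.4,139
right,gyro,6,resultant,-4.4,-37.0,28.2,15.6
right,gyro,6,z,2.2,-32.4,36.6,17.6
right,gyro,6,y,7.0,-45.2,59.2,53.0
right,gyro,6,x,17.4,-101,136,185
right,gyro,9,resultant,-4.0,-38.2,30.2,16.8
right,gyro,9,z,2.4,-32.4,37.2,18.0
right,gyro,9,y,8.2,-49.8,66.0,64.2
right,gyro,9,x,16.2,-104,136,189
right,gyro,12,resultant,-4.2,-37.6,29.4,16.2
right,gyro,12,z,2.6,-33.6,38.8,20.8
right,gyro,12,y,8.4,-48.6,65.6,62.6
right,gyro,12,x,19.4,-106,144,199
right,acc,0,resultant,-9.4,-39.6,21.0,18.2
right,acc,0,z,-54.6,NA,NA,NA
right,acc,0,y,-14.4,-47.6,19.0,26.2
right,acc,0,x,-158,NA,NA,NA
right,acc,3,resultant,-9.0,-71.0,53.0,72.4
right,acc,3,z,-60.2,NA,NA,NA
right,acc,3,y,-13.0,-40.2,14.4,18.8
right,acc,3,x,-73.2,NA,NA,NA
right,acc,6,resultant,-9.8,-35.4,15.8,14.0
right,acc,6,z,-66.2,NA,NA,NA
right,acc,6,y,-13.8,-42.2,14.4,20.6
right,acc,6,x,-104,NA,NA,NA
right,acc,9,resultant,-7.6,-36.6,21.2,15.0
right,acc,9,z,-50.8,NA,NA,NA
right,acc,9,y,-14.2,-43.4,15.0,22.0
right,acc,9,x,-116,NA,NA,NA
right,acc,12,resultant,-7.2,-38.8,24.2,17.4
right,acc,12,z,-60.4,NA,NA,NA
right,acc,12,y,-14.8,-45.8,16.4,24.4
right,acc,12,x,-140,NA,NA,NA
left,gyro,0,resultant,-3.4,-39.4,32.8,20.8
left,gyro,0,z,1.2,-34.2,36.4,19.2
left,gyro,0,y,4.8,-74.0,83.6,106
left,gyro,0,x,58.8,NA,NA,NA
left,gyro,3,resultant,-5.2,-34.4,23.8,12.8
left,gyro,3,z,0.4,-27.8,28.6,6.2
left,gyro,3,y,12.0,-48.0,72.0,68.4
left,gyro,3,x,70.2,NA,NA,NA
left,gyro,6,resultant,-3.0,-34.4,28.6,13.0
left,gyro,6,z,3.2,-28.6,34.8,11.8
left,gyro,6,y,13.4,-53.4,80.0,81.8
left,gyro,6,x,76.8,NA,NA,NA
left,gyro,9,resultant,-2.6,-36.0,30.8,15.2
left,gyro,9,z,3.6,-29.4,36.4,14.2
left,gyro,9,y,13.4,-55.8,82.6,86.8
left,gyro,9,x,72.0,NA,NA,NA
left,gyro,12,resultant,-2.6,-38.2,33.0,19.6
left,gyro,12,z,3.6,-30.8,38.2,17.4
left,gyro,12,y,14.2,-55.4,84.0,88.0
left,gyro,12,x,64.8,NA,NA,NA
left,acc,0,resultant,-11.0,-81.2,59.2,88.8
left,acc,0,z,-52.0,NA,NA,NA
left,acc,0,y,-10.4,-50.2,29.6,28.8
left,acc,0,x,-125,NA,NA,NA
left,acc,3,resultant,-14.4,-82.6,54.0,85.2
left,acc,3,z,-60.2,NA,NA,NA
left,acc,3,y,-16.8,-86.8,53.4,88.6
left,acc,3,x,-39.8,NA,NA,NA
left,acc,6,resultant,-13.2,-81.0,54.8,84.2
left,acc,6,z,-61.6,NA,NA,NA
left,acc,6,y,-13.6,-41.2,14.0,19.8
left,acc,6,x,-46.0,NA,NA,NA
left,acc,9,resultant,-11.4,-80.6,57.6,86.6
left,acc,9,z,-54.2,NA,NA,NA
left,acc,9,y,-12.6,-42.0,16.8,20.4
left,acc,9,x,-77.4,NA,NA,NA
left,acc,12,resultant,-11.0,-80.8,59.0,88.2
left,acc,12,z,-49.6,NA,NA,NA
left,acc,12,y,-12.6,-44.2,18.8,22.6
left,acc,12,x,-87.2,NA,NA,NA
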