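structure,role,side,subpoint,mean_x,sd_x,mean_y,sd_y,mean_z,sd_z
COC,origin,left,1,56.2,6.9,-49.5,6.7,-52.4,4.3
COC,origin,right,1,55.7,5.3,-50.6,6.0,51.3,4.4
COC,insertion,left,1,87.2,7.9,-56.5,6.8,-8.9,3.9
COC,insertion,left,2,75.3,8.3,-45.7,6.8,-8.8,3.7
COC,insertion,right,1,86.6,7.2,-56.1,8.4,6.4,4.3
COC,insertion,right,2,73.2,8.1,-44.6,6.0,5.5,5.1
ICM,origin,left,1,56.2,6.9,-49.5,6.7,-52.4,4.3
ICM,origin,left,2,16.0,7.2,-28.7,8.2,-28.9,3.9
ICM,origin,right,1,55.7,5.3,-50.6,6.0,51.3,4.4
ICM,origin,right,2,16.3,7.9,-29.4,7.9,28.7,4.4
ICM,insertion,midline,1,73.3,8.3,-39.6,6.6,-0.2,2.2
ICM,insertion,midline,2,52.5,6.6,-32.4,7.4,-0.1,2.0
PRM,origin,left,1,-7.9,4.0,-18.2,3.4,-20.5,2.4
PRM,origin,left,2,4.8,4.6,-5.0,3.3,-20.1,2.0
PRM,origin,right,1,-7.2,3.3,-16.9,3.6,19.1,3.1
PRM,origin,right,2,5.6,4.0,-3.7,2.8,19.3,2.5
PRM,insertion,midline,1,52.5,6.6,-32.4,7.4,-0.1,2.0
PRM,insertion,midline,2,48.9,7.0,-17.0,7.1,0.1,1.9
PVM,origin,left,1,15.2,7.4,-34.6,7.6,-32.4,4.7
PVM,origin,left,2,-1.3,5.0,-10.5,3.6,-16.1,2.9
PVM,origin,right,1,15.5,7.7,-34.5,6.5,32.6,5.0
PVM,origin,right,2,-1.3,4.8,-9.7,3.6,14.8,2.4
PAM,insertion,left,1,46.2,7.9,5.1,11.0,-7.3,3.5
PAM,insertion,right,1,45.8,7.9,4.8,11.0,6.7,2.6
PPM,insertion,midline,1,29.0,6.6,3.5,4.4,-0.2,1.6
PVaM,insertion,left,1,10.3,4.8,-5.1,5.2,-13.7,2.5
PVaM,insertion,left,2,21.2,5.4,-5.6,5.0,-9.2,2.7
PVaM,insertion,right,1,10.2,4.8,-5.6,4.9,13.9,2.4
PVaM,insertion,right,2,21.2,5.3,-5.9,4.9,8.7,4.4
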