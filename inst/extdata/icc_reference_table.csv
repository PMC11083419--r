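structure,role,side,subpoint,axis,estimate,ci_low,ci_high
COC,origin,left,1,x,0.7,0.13,0.9
COC,origin,left,1,y,0.83,0.5,0.95
COC,origin,left,1,z,0.71,0.11,0.91
COC,origin,right,1,x,0.43,0,0.79
COC,origin,right,1,y,0.94,0.58,0.98
COC,origin,right,1,z,0.46,0,0.83
COC,insertion,left,1,x,0.93,0.78,0.98
COC,insertion,left,1,y,0.91,0.72,0.97
COC,insertion,left,1,z,0.57,0,0.86
COC,insertion,left,2,x,0.48,0,0.82
COC,insertion,left,2,y,0.86,0.56,0.96
COC,insertion,left,2,z,0.56,0,0.86
COC,insertion,right,1,x,0.38,0,0.8
COC,insertion,right,1,y,0.67,0,0.9
COC,insertion,right,1,z,0.52,0,0.85
COC,insertion,right,2,x,0.24,0,0.7
COC,insertion,right,2,y,0.8,0.41,0.94
COC,insertion,right,2,z,0.67,0.01,0.9
ICM,origin,left,1,x,0.7,0.13,0.9
ICM,origin,left,1,y,0.83,0.5,0.95
ICM,origin,left,1,z,0.71,0.11,0.91
ICM,origin,left,2,x,0.89,0.6,0.97
ICM,origin,left,2,y,0.85,0.53,0.95
ICM,origin,left,2,z,0.95,0.84,0.99
ICM,origin,right,1,x,0.43,0,0.79
ICM,origin,right,1,y,0.94,0.58,0.98
ICM,origin,right,1,z,0.46,0,0.83
ICM,origin,right,2,x,0.5,0,0.84
ICM,origin,right,2,y,0.3,0,0.78
ICM,origin,right,2,z,0.47,0,0.83
ICM,insertion,midline,1,x,0.73,0.19,0.92
ICM,insertion,midline,1,y,0.87,0.56,0.96
ICM,insertion,midline,1,z,0,0,0.69
ICM,insertion,midline,2,x,0.9,0.68,0.97
ICM,insertion,midline,2,y,0.91,0.52,0.97
ICM,insertion,midline,2,z,0.22,0,0.75
PRM,origin,left,1,x,0.79,0.37,0.93
PRM,origin,left,1,y,0.84,0.5,0.95
PRM,origin,left,1,z,0.71,0.13,0.91
PRM,origin,left,2,x,0.68,0.09,0.89
PRM,origin,left,2,y,0.97,0.9,0.99
PRM,origin,left,2,z,0.71,0.13,0.91
PRM,origin,right,1,x,0.57,0,0.95
PRM,origin,right,1,y,0.83,0.48,0.94
PRM,origin,right,1,z,0.5,0,0.82
PRM,origin,right,2,x,0.43,0,0.81
PRM,origin,right,2,y,0.68,0.03,0.9
PRM,origin,right,2,z,0.48,0,0.81
PRM,insertion,midline,1,x,0.9,0.68,0.97
PRM,insertion,midline,1,y,0.91,0.52,0.97
PRM,insertion,midline,1,z,0.22,0,0.75
PRM,insertion,midline,2,x,0.97,0.9,0.99
PRM,insertion,midline,2,y,0.88,0.63,0.96
PRM,insertion,midline,2,z,0.44,0,0.82
PVM,origin,left,1,x,0.79,0.38,0.93
PVM,origin,left,1,y,0.95,0.73,0.99
PVM,origin,left,1,z,0.9,0.67,0.97
PVM,origin,left,2,x,0.62,0,0.88
PVM,origin,left,2,y,0.74,0.22,0.92
PVM,origin,left,2,z,0.82,0.46,0.94
PVM,origin,right,1,x,0.74,0.23,0.92
PVM,origin,right,1,y,0.82,0.46,0.94
PVM,origin,right,1,z,0.67,0.08,0.89
PVM,origin,right,2,x,0.68,0.04,0.9
PVM,origin,right,2,y,0.57,0,0.86
PVM,origin,right,2,z,0.13,0,0.73
PAM,insertion,left,1,x,0.96,0.78,0.99
PAM,insertion,left,1,y,0.81,0.39,0.94
PAM,insertion,left,1,z,0.83,0.5,0.95
PAM,insertion,right,1,x,0.97,0.69,0.99
PAM,insertion,right,1,y,0.81,0.35,0.94
PAM,insertion,right,1,z,0.47,0,0.82
PPM,insertion,midline,1,x,0.94,0.81,0.98
PPM,insertion,midline,1,y,0.85,0.54,0.95
PPM,insertion,midline,1,z,0.82,0.45,0.94
PVaM,insertion,left,1,x,0.78,0.36,0.93
PVaM,insertion,left,1,y,0.85,0.13,0.96
PVaM,insertion,left,1,z,0.89,0.67,0.97
PVaM,insertion,left,2,x,0.92,0.75,0.97
PVaM,insertion,left,2,y,0.87,0.15,0.96
PVaM,insertion,left,2,z,0.5,0,0.84
PVaM,insertion,right,1,x,0.85,0.55,0.95
PVaM,insertion,right,1,y,0.82,0.12,0.95
PVaM,insertion,right,1,z,0.95,0.85,0.98
PVaM,insertion,right,2,x,0.89,0.56,0.97
PVaM,insertion,right,2,y,0.84,0.14,0.96
PVaM,insertion,right,2,z,0.74,0.23,0.91
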