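stage,predictor,B,SE,wald,p,or,ci_lo,ci_hi
wk2,duration_days,-0.124,0.045,7.563,0.006,0.884,0.809,0.965
wk2,mh_area_um2,0.001,0.000,8.593,0.003,1.001,1.000,1.001
wk2,bd_um,-0.033,0.014,5.112,0.024,0.968,0.941,0.996
mo3,ez_defect_um,-0.012,0.005,6.248,0.012,0.988,0.979,0.997
mo3,mld_um,-0.053,0.023,5.477,0.019,0.948,0.906,0.991
mo3,rate_mh,-0.007,0.004,3.660,0.050,0.993,0.986,1.000
mo3,rate_pct_ez,0.261,0.133,3.855,0.048,1.298,1.001,1.685
mo12,ez_defect_um,0.017,0.009,3.903,0.048,1.017,1.000,1.034
mo12,pseudocyst_area_um2,-0.001,0.000,4.968,0.026,0.999,0.999,1.000
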