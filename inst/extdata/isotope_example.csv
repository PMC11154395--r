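sample_id,time_h,matrix,replicate,cu65_ug,cu63_ug,dry_weight_g
T01,3,tissue,1,1.82,0.41,0.212
T02,3,tissue,2,1.75,0.38,0.198
T03,3,tissue,3,1.91,0.44,0.225
T04,6,tissue,1,3.40,0.40,0.205
T05,6,tissue,2,3.22,0.37,0.190
T06,6,tissue,3,3.55,0.43,0.218
T07,12,tissue,1,6.71,0.42,0.210
T08,12,tissue,2,6.38,0.39,0.201
T09,12,tissue,3,6.95,0.45,0.220
W01,0,water,1,15.8,0.9,
W02,6,water,1,15.1,0.9,
W03,12,water,1,14.6,0.8,
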