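"rf_field_hz","offset_hz","attenuation","sigma"
180,35000,0.976823285564908,0.01
180,30000,0.991115095393125,0.01
180,25000,0.971947434649389,0.01
180,20000,1.0100482954365,0.01
180,15000,0.985163003789388,0.01
180,10000,0.981679059804056,0.01
180,5000,0.923584587500615,0.01
180,0,0.95586677221845,0.01
180,-5000,0.966900115043281,0.01
180,-10000,1.00533178052777,0.01
180,-15000,0.996882354865465,0.01
180,-20000,1.00672104361785,0.01
180,-25000,0.999386612671427,0.01
180,-30000,1.00355738148146,0.01
180,-35000,1.00181715412035,0.01
350,35000,0.995162108794303,0.01
350,30000,0.975791302972529,0.01
350,25000,0.972774390506485,0.01
350,20000,0.982043471059911,0.01
350,15000,0.981112627063062,0.01
350,10000,0.931271332103287,0.01
350,5000,0.805384148130151,0.01
350,0,0.842630491573896,0.01
350,-5000,0.930836232612074,0.01
350,-10000,0.975566113200109,0.01
350,-15000,1.00365638544556,0.01
350,-20000,0.973705308848987,0.01
350,-25000,0.997407713856796,0.01
350,-30000,1.00209795213774,0.01
350,-35000,0.995974137622954,0.01
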