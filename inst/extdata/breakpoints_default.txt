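# Default PM2.5 breakpoint tables (identical to the tables embedded in the
# package). Format: "scheme: <name>" then rows
# conc_lo,conc_hi,index_lo,index_hi,label
scheme: AQI
0.0,12.0,0,50,good
12.1,35.4,51,100,moderate
35.5,55.4,101,150,unhealthy for sensitive groups
55.5,150.4,151,200,unhealthy
150.5,250.4,201,300,very unhealthy
250.5,350.4,301,400,hazardous
350.5,500.4,401,500,hazardous

scheme: WAQA
0.0,12.0,0,50,good
12.1,20.4,51,100,moderate
20.5,35.4,101,150,unhealthy for sensitive groups
35.5,80.4,151,200,unhealthy
80.5,140.4,201,300,very unhealthy
140.5,250.4,301,500,hazardous
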